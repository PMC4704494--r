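#!/usr/bin/env Rscript
# Image branch of the pipeline: render synthetic two-channel wells with
# contrasting phenotypes (vehicle-like, apoptotic-like small bright nuclei,
# enlarged nuclei, elongated cells), segment nuclei by adaptive
# thresholding, propagate cell bodies from the nuclear seeds, extract
# per-cell features and aggregate to well vectors. Writes the well-level
# feature table and a segmentation audit against the planted ground truth.

suppressMessages(library(chemgenmap))
dir.create("results", showWarnings = FALSE)

conditions <- list(
  vehicle   = list(n_cells = 30, nuclear_radius = 6, elongation = 1.0),
  apoptotic = list(n_cells = 18, nuclear_radius = 3.5, elongation = 1.0,
                   dna_level = 0.95),
  enlarged  = list(n_cells = 12, nuclear_radius = 9, elongation = 1.0),
  elongated = list(n_cells = 15, nuclear_radius = 6, elongation = 2.5)
)

rows <- list(); audit <- list()
for (nm in names(conditions)) {
  p <- conditions[[nm]]
  img <- do.call(gen_well_images, c(p, list(image_size = 448,
                                            texture_sd = 0.01,
                                            seed = match(nm, names(conditions)))))
  out <- process_well(img$dna, img$actin)
  rows[[nm]] <- c(condition = nm, round(out$well_vector, 4))
  audit[[nm]] <- data.frame(condition = nm, planted = p$n_cells,
                            segmented = n_objects(out$nuclei))
  cat(sprintf("%-10s planted %2d cells -> segmented %2d; mean nuclear radius %.2f px\n",
              nm, p$n_cells, n_objects(out$nuclei),
              mean(out$records$nuc.radius_mean)))
}

tab <- do.call(rbind, lapply(rows, function(r)
  as.data.frame(as.list(r), check.names = FALSE)))
utils::write.table(tab, "results/well_features_imaging.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(do.call(rbind, audit), "results/segmentation_audit.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/well_features_imaging.tsv, results/segmentation_audit.tsv\n")
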
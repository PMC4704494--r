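#!/usr/bin/env Rscript
# Simulate the reference screen used throughout the analysis: 50 compounds x
# 8 isogenic lines x 2 replicates on 384-well plates, 10 glog-scale features
# with a sparse planted interaction tensor (2% of cells, |gamma| in
# [0.5, 2], noise sd 0.2). Writes the design, the two replicate feature
# tables and the ground truth under results/.

suppressMessages(library(chemgenmap))
dir.create("results", showWarnings = FALSE)

design <- gen_screen_design(n_compounds = 50, n_lines = 8, n_replicates = 2,
                            plate_format = 384, seed = 101)
ft <- gen_feature_tables(design, n_features = 10, seed = 101)

write_screen_tsv(design, "results/screen_design.tsv")
for (r in names(ft$tables))
  write_screen_tsv(ft$tables[[r]], sprintf("results/features_%s.tsv", r))

truth <- ft$truth
planted <- which(truth$gamma != 0, arr.ind = TRUE)
write_truth_json(list(
  sigma = truth$sigma, seed = truth$seed,
  n_planted = nrow(planted),
  planted = data.frame(
    compound = rownames(truth$gamma)[planted[, 1]],
    line = colnames(truth$gamma)[planted[, 2]],
    feature = dimnames(truth$gamma)[[3]][planted[, 3]],
    gamma = truth$gamma[planted])),
  "results/ground_truth.json")

cat(sprintf("screen: %d wells on %d plates; %d features; %d planted interactions\n",
            nrow(design), length(unique(design$plate)),
            length(truth$feature_names), nrow(planted)))
cat("wrote results/screen_design.tsv, results/features_rep*.tsv, results/ground_truth.json\n")
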
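#' Crop a fixed margin from every side of an image
#'
#' Removes border pixels, which carry lower illumination in wide-field
#' acquisition; default margin 150 px matches 2048 x 2048 input tiles.
#'
#' @param image 2-D numeric matrix.
#' @param margin pixels to remove on each side.
#' @return the cropped matrix; pixel values are untouched.
#' @export
crop_border <- function(image, margin = 150) {
  stopifnot(is.matrix(image), margin >= 0)
  if (margin == 0) return(image)
  if (nrow(image) <= 2 * margin || ncol(image) <= 2 * margin)
    stop(sprintf("margin %d too large for a %d x %d image",
                 margin, nrow(image), ncol(image)))
  image[(margin + 1):(nrow(image) - margin),
        (margin + 1):(ncol(image) - margin)]
}

#' Segment nuclei by adaptive thresholding of the DNA channel
#'
#' Local-mean adaptive thresholding with a square moving window (default
#' 10 x 10 px) and a small positive offset so that flat images yield no
#' foreground, followed by hole filling and connected-component labelling.
#'
#' @param dna_image 2-D numeric matrix (DNA channel).
#' @param window side of the thresholding window in pixels (default 10).
#' @param offset threshold offset above the local mean.
#' @param min_area discard components smaller than this (speckle guard).
#' @return integer label matrix (0 = background) of class \code{label_mask};
#'   labels are consecutive positive integers.
#' @export
segment_nuclei <- function(dna_image, window = 10, offset = 0.05,
                           min_area = 9) {
  stopifnot(is.matrix(dna_image), window >= 2)
  img <- EBImage::Image(dna_image)
  half <- max(1L, as.integer(window / 2))
  mask <- EBImage::thresh(img, w = half, h = half, offset = offset)
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  m <- EBImage::imageData(lab)
  if (max(m) > 0 && min_area > 0) {
    sizes <- tabulate(m[m > 0])
    drop <- which(sizes < min_area)
    if (length(drop)) m[m %in% drop] <- 0L
    m <- relabel_consecutive(m)
  }
  as_label_mask(m, channel = "dna")
}

#' Segment cell bodies by Voronoi-style propagation from nuclear seeds
#'
#' Extends the nuclei labels into an adaptive threshold mask of the actin
#' channel (window default 50 px, union with the nuclei so every seed is
#' covered) using the Voronoi-based propagation algorithm
#' (\code{EBImage::propagate}). Every nucleus yields exactly one cell region;
#' regions are disjoint; a connected actin blob containing several nuclei is
#' partitioned between them.
#'
#' @param nuclei label mask from \code{\link{segment_nuclei}}.
#' @param actin_image 2-D numeric matrix, same dimensions as \code{nuclei}.
#' @param window actin threshold window in pixels.
#' @param offset actin threshold offset.
#' @param lambda regularisation of the propagation metric (trade-off between
#'   intensity gradients and euclidean distance).
#' @return cell label matrix of class \code{label_mask}; label i is the cell
#'   grown from nucleus i.
#' @export
segment_cells <- function(nuclei, actin_image, window = 50, offset = 0.05,
                          lambda = 1e-4) {
  stopifnot(is.matrix(actin_image))
  if (!all(dim(nuclei) == dim(actin_image)))
    stop("nuclei mask and actin image dimensions differ")
  if (max(nuclei) == 0)
    return(as_label_mask(matrix(0L, nrow(nuclei), ncol(nuclei)),
                         channel = "actin"))
  img <- EBImage::Image(actin_image)
  half <- max(1L, as.integer(window / 2))
  amask <- EBImage::imageData(EBImage::thresh(img, w = half, h = half,
                                              offset = offset))
  amask[nuclei > 0] <- 1                       # seeds always inside the mask
  cells <- EBImage::propagate(img, seeds = EBImage::Image(unclass(nuclei)),
                              mask = EBImage::Image(amask), lambda = lambda)
  as_label_mask(EBImage::imageData(cells), channel = "actin")
}

as_label_mask <- function(m, channel = NA_character_) {
  storage.mode(m) <- "integer"
  structure(m, channel = channel, class = c("label_mask", "matrix", "array"))
}

relabel_consecutive <- function(m) {
  u <- sort(unique(m[m > 0]))
  if (length(u)) m[m > 0] <- match(m[m > 0], u)
  m
}

#' Number of labelled objects in a mask
#' @param mask a \code{label_mask}.
#' @return integer count (the cell-count proxy for nuclei masks).
#' @export
n_objects <- function(mask) as.integer(max(mask))

#' Extract per-cell morphology, intensity and texture features
#'
#' For every labelled cell, computes nuclear and cell-body feature families:
#' shape (area, perimeter, equivalent radius, eccentricity, major axis),
#' intensity statistics (mean, sd, total, upper quantile) and Haralick
#' textures (32 grey levels, 1-px offset, directions averaged) on the DNA
#' channel for the nucleus and on the actin channel for the cell body.
#'
#' @param nuclei,cells label masks with matching label sets
#'   (cell i contains nucleus i).
#' @param dna_image,actin_image intensity matrices.
#' @return \code{data.frame}, one row per cell, first column \code{cell_id}.
#' @export
extract_cell_features <- function(nuclei, cells, dna_image, actin_image) {
  if (max(nuclei) != max(cells))
    stop("inconsistent masks: nuclei and cell label counts differ")
  n <- max(nuclei)
  if (n == 0) return(empty_cell_features())
  region_features <- function(mask, img, prefix) {
    sh <- EBImage::computeFeatures.shape(unclass(mask))
    mo <- EBImage::computeFeatures.moment(unclass(mask), img)
    ba <- EBImage::computeFeatures.basic(unclass(mask), img)
    ha <- EBImage::computeFeatures.haralick(unclass(mask), img,
                                            haralick.nbins = 32,
                                            haralick.scales = 1)
    out <- data.frame(
      area = sh[, "s.area"],
      perimeter = sh[, "s.perimeter"],
      radius_mean = sh[, "s.radius.mean"],
      eccentricity = mo[, "m.eccentricity"],
      majoraxis = mo[, "m.majoraxis"],
      int_mean = ba[, "b.mean"],
      int_sd = ba[, "b.sd"],
      int_q95 = ba[, "b.q095"],
      haralick_con = ha[, "h.con.s1"],
      haralick_cor = ha[, "h.cor.s1"],
      haralick_ent = ha[, "h.ent.s1"],
      haralick_asm = ha[, "h.asm.s1"]
    )
    names(out) <- paste(prefix, names(out), sep = ".")
    out
  }
  nf <- region_features(nuclei, dna_image, "nuc")
  cf <- region_features(cells, actin_image, "cell")
  cbind(data.frame(cell_id = seq_len(n)), nf, cf)
}

empty_cell_features <- function() {
  nm <- c("area", "perimeter", "radius_mean", "eccentricity", "majoraxis",
          "int_mean", "int_sd", "int_q95",
          "haralick_con", "haralick_cor", "haralick_ent", "haralick_asm")
  cols <- c("cell_id", paste("nuc", nm, sep = "."), paste("cell", nm, sep = "."))
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  df
}

#' Aggregate per-cell features into a well-level feature vector
#'
#' Cell count (number of segmented nuclei) plus the mean of every per-cell
#' feature; intensity features additionally get a cell-to-cell standard
#' deviation. An empty record list yields count 0 and NA aggregates.
#'
#' @param records \code{data.frame} from \code{\link{extract_cell_features}}.
#' @return named numeric vector starting with \code{cell_number}.
#' @export
aggregate_well <- function(records) {
  feat_cols <- setdiff(names(records), "cell_id")
  if (nrow(records) == 0) {
    means <- stats::setNames(rep(NA_real_, length(feat_cols)), feat_cols)
  } else {
    means <- vapply(records[feat_cols], mean, numeric(1))
  }
  int_cols <- grep("int_", feat_cols, value = TRUE)
  sds <- if (nrow(records) == 0)
    stats::setNames(rep(NA_real_, length(int_cols)), int_cols)
  else vapply(records[int_cols], stats::sd, numeric(1))
  names(sds) <- paste0(int_cols, ".sd")
  c(cell_number = nrow(records), means, sds)
}

#' Segment and featurise one synthetic or real two-channel well
#'
#' Convenience wrapper: optional border crop, nuclei segmentation, cell
#' propagation, per-cell feature extraction, well aggregation.
#'
#' @param dna,actin intensity matrices.
#' @param margin crop margin (0 = no crop).
#' @param window nuclei threshold window.
#' @return list with \code{nuclei}, \code{cells}, \code{records},
#'   \code{well_vector}.
#' @export
process_well <- function(dna, actin, margin = 0, window = 10) {
  if (margin > 0) {
    dna <- crop_border(dna, margin)
    actin <- crop_border(actin, margin)
  }
  nuc <- segment_nuclei(dna, window = window)
  cel <- segment_cells(nuc, actin)
  rec <- extract_cell_features(nuc, cel, dna, actin)
  list(nuclei = nuc, cells = cel, records = rec,
       well_vector = aggregate_well(rec))
}
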
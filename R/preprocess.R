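#' Generalized logarithm transform
#'
#' Variance-stabilising transform glog(x; c) = log2((x + sqrt(x^2 + c^2))/2).
#' Strictly increasing, defined at 0 (glog(0; c) = log2(c/2)), and
#' asymptotically log2(x) for x >> c.
#'
#' @param x numeric values (any sign, typically nonnegative measurements).
#' @param c calibration constant (> 0); default 1 for count-like features.
#' @return transformed values.
#' @export
glog_transform <- function(x, c = 1) {
  if (!is.numeric(c) || length(c) != 1 || c <= 0) stop("c must be > 0")
  log2((x + sqrt(x^2 + c^2)) / 2)
}

#' Inverse of \code{\link{glog_transform}}
#' @param y transformed values.
#' @param c calibration constant used in the forward transform.
#' @return original-scale values.
#' @export
glog_inverse <- function(y, c = 1) {
  if (c <= 0) stop("c must be > 0")
  u <- 2^(y + 1)
  (u^2 - c^2) / (2 * u)
}

#' QC rule set for well-level tables
#'
#' Defaults flag wells that look like blank images (no cells and near-zero
#' intensity readouts) and, when a saturation column is present, wells with a
#' saturated-pixel fraction above 5%.
#'
#' @param max_cells_blank glog cell-number at/below which a well counts as
#'   empty.
#' @param max_intensity_blank mean intensity-feature value at/below which a
#'   well counts as dark.
#' @param max_saturated_frac saturation cutoff (used if a
#'   \code{saturated_frac} column exists).
#' @return list of thresholds.
#' @export
qc_rules <- function(max_cells_blank = 0, max_intensity_blank = 1e-6,
                     max_saturated_frac = 0.05) {
  list(max_cells_blank = max_cells_blank,
       max_intensity_blank = max_intensity_blank,
       max_saturated_frac = max_saturated_frac)
}

#' Flag wells failing quality control
#'
#' Sets the logical \code{qc_pass} column; flagged wells must be excluded
#' from all downstream statistics (see \code{\link{estimate_interactions}},
#' which drops them).
#'
#' @param table well feature table (annotation columns + feature columns).
#' @param rules list from \code{\link{qc_rules}}.
#' @return the table with \code{qc_pass} filled in and attribute
#'   \code{n_flagged}.
#' @export
qc_wells <- function(table, rules = qc_rules()) {
  feats <- feature_columns(table)
  int_cols <- grep("\\.int", feats, value = TRUE)
  blank <- rep(FALSE, nrow(table))
  if ("cell_number" %in% feats) {
    blank <- table$cell_number <= rules$max_cells_blank
    if (length(int_cols))
      blank <- blank &
        rowMeans(as.matrix(table[int_cols])) <= rules$max_intensity_blank
  }
  sat <- if ("saturated_frac" %in% names(table))
    table$saturated_frac > rules$max_saturated_frac else FALSE
  table$qc_pass <- !(blank | sat)
  attr(table, "n_flagged") <- sum(!table$qc_pass)
  table
}

annotation_columns <- c("plate", "well", "row", "col", "compound_id",
                        "conc_uM", "cell_line", "replicate", "role",
                        "qc_pass", "bad_injected", "saturated_frac")

#' Feature columns of a well table
#' @param table well feature table.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), annotation_columns)
}

#' Per-feature correlation between two replicate tables
#'
#' Wells are matched on (plate-series position): by \code{compound_id},
#' \code{cell_line} and \code{well} annotation when present, otherwise by
#' row order. Constant features have undefined correlation and are ranked
#' last.
#'
#' @param rep1,rep2 well feature tables or plain wells x features matrices.
#' @param method "pearson" or "spearman".
#' @return \code{data.frame} (feature, cor, rank) sorted by rank.
#' @export
replicate_correlation <- function(rep1, rep2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- match_replicates(rep1, rep2)
  if (nrow(m$x) == 0) stop("no matched wells between replicates")
  cors <- vapply(seq_len(ncol(m$x)), function(j) {
    x <- m$x[, j]; y <- m$y[, j]
    if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0)
      return(NA_real_)
    stats::cor(x, y, method = method, use = "pairwise.complete.obs")
  }, numeric(1))
  out <- data.frame(feature = colnames(m$x), cor = cors,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$cor, out$feature, na.last = TRUE), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

match_replicates <- function(rep1, rep2) {
  if (is.matrix(rep1) && is.matrix(rep2)) {
    feats <- intersect(colnames(rep1), colnames(rep2))
    return(list(x = rep1[, feats, drop = FALSE],
                y = rep2[, feats, drop = FALSE]))
  }
  feats <- intersect(feature_columns(rep1), feature_columns(rep2))
  key <- function(d) paste(d$compound_id, d$cell_line, d$well)
  k1 <- key(rep1); k2 <- key(rep2)
  common <- intersect(k1, k2)
  list(x = as.matrix(rep1[match(common, k1), feats, drop = FALSE]),
       y = as.matrix(rep2[match(common, k2), feats, drop = FALSE]))
}

#' Stepwise selection of informative, non-redundant features
#'
#' Starting from the cell-number feature, each iteration regresses every
#' feature on the selected set (ordinary least squares with intercept,
#' fitted within each replicate separately) and scores it by the Pearson
#' correlation between the two replicates' residual vectors -- a surrogate
#' for reproducible information not yet captured. The candidate with the
#' highest score is selected; the procedure stops when the percentage of
#' positive residual correlations over all features falls below 50%.
#' Already-selected features have exactly zero residuals, so their
#' correlation is undefined and counts as not positive while remaining in
#' the denominator. Ties break by feature name.
#'
#' @param rep1,rep2 well feature tables or wells x features matrices with
#'   matched rows.
#' @param start_feature name of the initial feature (default
#'   \code{"cell_number"}).
#' @param stop_frac stopping threshold on the fraction of positive residual
#'   correlations (default 0.5).
#' @param max_iter safety bound on the number of selections.
#' @return list of class \code{feature_selection} with \code{selected}
#'   (ordered), \code{scores} (per-iteration score of the pick),
#'   \code{frac_positive} (per-iteration stopping diagnostic, including the
#'   final one that triggered the stop).
#' @export
select_features <- function(rep1, rep2, start_feature = "cell_number",
                            stop_frac = 0.5, max_iter = Inf) {
  m <- match_replicates(rep1, rep2)
  X1 <- m$x; X2 <- m$y
  feats <- colnames(X1)
  if (!start_feature %in% feats)
    stop(sprintf("start feature '%s' not present", start_feature))
  selected <- start_feature
  pick_scores <- numeric(0)
  fracs <- numeric(0)
  repeat {
    s1 <- residual_scores(X1, X2, selected)
    frac_pos <- sum(s1 > 0, na.rm = TRUE) / length(feats)
    fracs <- c(fracs, frac_pos)
    if (frac_pos < stop_frac || length(selected) >= length(feats) ||
        length(selected) - 1 >= max_iter)
      break
    cand <- setdiff(feats, selected)
    sc <- s1[cand]
    if (all(is.na(sc))) break
    best <- max(sc, na.rm = TRUE)
    pick <- sort(cand[!is.na(sc) & sc == best])[1]
    selected <- c(selected, pick)
    pick_scores <- c(pick_scores, best)
  }
  structure(list(selected = selected,
                 scores = stats::setNames(pick_scores, selected[-1]),
                 frac_positive = fracs),
            class = "feature_selection")
}

# residual correlations of every feature after OLS on the selected set,
# fitted per replicate; exact-fit features return NA
residual_scores <- function(X1, X2, selected) {
  res_of <- function(X) {
    Z <- cbind(1, X[, selected, drop = FALSE])
    qr_z <- qr(Z)
    if (qr_z$rank < ncol(Z)) {
      # collinear selected features: drop dependent columns with a warning
      keep <- qr_z$pivot[seq_len(qr_z$rank)]
      warning("collinear selected features; dropping dependent predictors")
      qr_z <- qr(Z[, keep, drop = FALSE])
    }
    qr.resid(qr_z, X)
  }
  R1 <- res_of(X1); R2 <- res_of(X2)
  vapply(seq_len(ncol(X1)), function(j) {
    r1 <- R1[, j]; r2 <- R2[, j]
    if (stats::sd(r1) < 1e-10 || stats::sd(r2) < 1e-10) return(NA_real_)
    stats::cor(r1, r2)
  }, numeric(1)) |> stats::setNames(colnames(X1))
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("feature_selection: %d features selected\n", length(x$selected)))
  cat(paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("final positive-residual-correlation fraction: %.3f\n",
              utils::tail(x$frac_positive, 1)))
  invisible(x)
}

#' Default phenoprint category map
#'
#' Maps feature names to the five phenoprint categories by name pattern:
#' cell number; DNA texture/intensity (\code{dna.*}); nuclear shape
#' (\code{nuc.*}); cell shape (\code{cell.*}); actin texture/intensity
#' (\code{act.*}).
#' @param features character vector of feature names.
#' @return named character vector feature -> category (NA when unmapped).
#' @export
default_category_map <- function(features) {
  cat <- rep(NA_character_, length(features))
  cat[features == "cell_number"] <- "cell number"
  cat[grepl("^dna\\.", features)] <- "DNA texture/intensity"
  cat[grepl("^nuc\\.", features)] <- "nuclear shape"
  cat[grepl("^cell\\.", features)] <- "cell shape"
  cat[grepl("^act\\.", features)] <- "actin texture/intensity"
  stats::setNames(cat, features)
}

#' Group selected features into a phenoprint (radar chart) specification
#'
#' @param selected character vector of selected features.
#' @param category_map named vector feature -> category; default maps by name
#'   pattern via \code{\link{default_category_map}}.
#' @return list of class \code{phenoprint_spec}: \code{features} (ordered by
#'   category), \code{category} per feature, \code{categories} (the five
#'   groups in display order), \code{angles} (radial positions in radians).
#' @export
group_phenoprint <- function(selected, category_map = NULL) {
  if (is.null(category_map)) category_map <- default_category_map(selected)
  cats <- category_map[selected]
  if (anyNA(cats))
    stop(sprintf("unmapped feature(s): %s",
                 paste(selected[is.na(cats)], collapse = ", ")))
  order_cats <- c("cell number", "DNA texture/intensity", "nuclear shape",
                  "cell shape", "actin texture/intensity")
  extra <- setdiff(unique(cats), order_cats)
  order_cats <- c(order_cats, extra)
  o <- order(match(cats, order_cats), selected)
  feats <- selected[o]
  structure(list(features = feats, category = cats[o],
                 categories = intersect(order_cats, cats),
                 angles = stats::setNames(
                   2 * pi * (seq_along(feats) - 1) / length(feats), feats)),
            class = "phenoprint_spec")
}
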
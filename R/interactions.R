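#' Range-normalize glog cell numbers within one cell line
#'
#' Linear rescaling anchored on the per-line median of negative-control
#' (vehicle) wells, mapped to 1, and the kill-reference compound value,
#' mapped to 0. Values below 0 and above 1 are possible; this accounts for
#' differing proliferation rates of the isogenic lines.
#'
#' @param values glog cell numbers.
#' @param negctrl_median per-line median of the vehicle wells.
#' @param kill_ref per-line kill-reference anchor value.
#' @return normalized values: (values - kill_ref) / (negctrl_median - kill_ref).
#' @export
normalize_cell_number <- function(values, negctrl_median, kill_ref) {
  if (negctrl_median == kill_ref)
    stop("degenerate normalization range: anchors are equal")
  (values - kill_ref) / (negctrl_median - kill_ref)
}

#' Apply per-line cell-number normalization to replicate tables
#'
#' For every cell line and replicate, anchors are the median of vehicle-well
#' cell numbers and the median of kill-reference-well cell numbers.
#'
#' @param tables list of well feature tables (one per replicate).
#' @param feature feature to normalize (default \code{"cell_number"}).
#' @return the tables with the feature rescaled.
#' @export
normalize_cell_feature <- function(tables, feature = "cell_number") {
  lapply(tables, function(tb) {
    for (cl in unique(tb$cell_line)) {
      in_line <- tb$cell_line == cl
      neg <- stats::median(tb[in_line & tb$role == "vehicle", feature])
      kill <- stats::median(tb[in_line & tb$role == "kill_reference", feature])
      tb[in_line, feature] <-
        normalize_cell_number(tb[in_line, feature], neg, kill)
    }
    tb
  })
}

#' Median polish of a two-way table
#'
#' Robust L1 decomposition of a compounds x lines matrix into overall, row
#' (compound) and column (line) effects plus residuals by alternately
#' subtracting row and column medians; iteration stops when the relative
#' change in the sum of absolute residuals, |dS|/S, falls below \code{tol}
#' (default 1e-4). Missing entries are ignored by the medians. The residuals
#' are the interaction coefficients.
#'
#' @param M numeric matrix (>= 1 row and column).
#' @param tol convergence threshold on |dS|/S.
#' @param max_iter iteration cap.
#' @return list with \code{overall}, \code{row} (compound effects),
#'   \code{col} (line effects), \code{residuals}, \code{iterations},
#'   \code{converged}. Reconstruction identity:
#'   \code{M == overall + row[i] + col[j] + residuals[i, j]}.
#' @export
median_polish <- function(M, tol = 1e-4, max_iter = 100L) {
  stopifnot(is.matrix(M), nrow(M) >= 1, ncol(M) >= 1)
  if (any(apply(M, 1, function(r) all(is.na(r)))))
    stop("all-missing row")
  if (any(apply(M, 2, function(c) all(is.na(c)))))
    stop("all-missing column")
  z <- M
  r <- numeric(nrow(M)); c_ <- numeric(ncol(M)); t_ <- 0
  oldsum <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    rdelta <- apply(z, 1, stats::median, na.rm = TRUE)
    z <- z - rdelta
    r <- r + rdelta
    delta <- stats::median(c_)
    c_ <- c_ - delta
    t_ <- t_ + delta
    cdelta <- apply(z, 2, stats::median, na.rm = TRUE)
    z <- sweep(z, 2, cdelta)
    c_ <- c_ + cdelta
    delta <- stats::median(r)
    r <- r - delta
    t_ <- t_ + delta
    newsum <- sum(abs(z), na.rm = TRUE)
    if (newsum == 0 || abs(newsum - oldsum) < tol * newsum) {
      converged <- TRUE
      break
    }
    oldsum <- newsum
  }
  names(r) <- rownames(M); names(c_) <- colnames(M)
  dimnames(z) <- dimnames(M)
  list(overall = t_, row = r, col = c_, residuals = z,
       iterations = iter, converged = converged)
}

#' Estimate chemical-genetic interaction coefficients
#'
#' For each feature and replicate, wells passing QC are collapsed to one
#' value per (compound, cell line) by the median, and the resulting
#' compounds x lines matrix is median-polished; the residuals are the
#' interaction coefficients. Cell-number normalization (if wanted) must be
#' applied beforehand via \code{\link{normalize_cell_feature}}.
#'
#' @param tables list of well feature tables, one per replicate.
#' @param features features to analyse (default: all feature columns).
#' @param tol median-polish convergence threshold.
#' @return object of class \code{interaction_result}: \code{pi} (array
#'   compound x line x feature x replicate of interaction coefficients),
#'   \code{overall} (feature x replicate), \code{compound_effects} and
#'   \code{line_effects} arrays, \code{compounds}, \code{lines},
#'   \code{features}, \code{roles} (role of each compound id).
#' @export
estimate_interactions <- function(tables, features = NULL, tol = 1e-4) {
  stopifnot(is.list(tables), length(tables) >= 1)
  tables <- lapply(tables, function(tb) {
    if (!all(is.na(tb$qc_pass))) tb[tb$qc_pass %in% TRUE, , drop = FALSE]
    else tb
  })
  if (is.null(features)) features <- feature_columns(tables[[1]])
  all_tb <- do.call(rbind, lapply(tables, as.data.frame))
  compounds <- sort(unique(all_tb$compound_id))
  lines <- sort(unique(all_tb$cell_line))
  roles <- stats::setNames(
    all_tb$role[match(compounds, all_tb$compound_id)], compounds)
  R <- length(tables)
  D <- length(compounds); L <- length(lines); F <- length(features)
  pi_arr <- array(NA_real_, dim = c(D, L, F, R),
                  dimnames = list(compounds, lines, features,
                                  paste0("rep", seq_len(R))))
  overall <- matrix(NA_real_, F, R, dimnames = list(features, NULL))
  ceff <- array(NA_real_, dim = c(D, F, R), dimnames = list(compounds, features, NULL))
  leff <- array(NA_real_, dim = c(L, F, R), dimnames = list(lines, features, NULL))
  for (ri in seq_len(R)) {
    tb <- tables[[ri]]
    di <- factor(tb$compound_id, levels = compounds)
    ci <- factor(tb$cell_line, levels = lines)
    for (fi in seq_len(F)) {
      M <- tapply(tb[[features[fi]]], list(di, ci), stats::median)
      mp <- median_polish(unclass(M), tol = tol)
      pi_arr[, , fi, ri] <- mp$residuals
      overall[fi, ri] <- mp$overall
      ceff[, fi, ri] <- mp$row
      leff[, fi, ri] <- mp$col
    }
  }
  structure(list(pi = pi_arr, overall = overall,
                 compound_effects = ceff, line_effects = leff,
                 compounds = compounds, lines = lines, features = features,
                 roles = roles, n_replicates = R),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(
    "interaction_result: %d compounds x %d lines x %d features x %d replicates\n",
    length(x$compounds), length(x$lines), length(x$features), x$n_replicates))
  if (!is.null(x$calls))
    cat(sprintf("  %d significant interactions at FDR %.3g\n",
                sum(x$calls$significant, na.rm = TRUE), x$fdr))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (delegates to \code{stats::p.adjust}).
#' @param p p-values in [0, 1].
#' @return adjusted p-values (>= raw, monotone in sorted order).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Test interaction coefficients with a moderated t-test
#'
#' For each feature, the replicate interaction coefficients of every
#' (compound, line) unit are tested against mu = 0 with the empirical-Bayes
#' moderated one-sample t (\code{\link{moderated_t_test}}); p-values are
#' BH-adjusted per feature across all units of that feature's interaction
#' matrix. Units missing in any replicate are excluded listwise.
#'
#' @param result an \code{interaction_result}.
#' @param fdr significance cutoff on adjusted p-values (default 0.01).
#' @param params \code{"estimate"} or a list with \code{d0}, \code{s02}.
#' @param prior_scope where the variance prior is estimated:
#'   \code{"global"} (default) fits a single prior degrees of freedom d0
#'   across the units of all features, with a feature-specific prior scale
#'   (each feature's sample variances are standardised by their median
#'   before pooling, and the fitted s0^2 is rescaled back per feature).
#'   With few replicates this is far more stable than refitting the whole
#'   prior per feature matrix (\code{prior_scope = "feature"}), and the
#'   per-feature scale tolerates features on different measurement scales,
#'   such as the range-normalised cell number.
#' @return the \code{interaction_result} with a \code{calls} data.frame
#'   (compound, line, feature, role, mean_pi, t, p, p_adj, significant) and
#'   \code{fdr} recorded.
#' @export
test_interactions <- function(result, fdr = 0.01, params = "estimate",
                              prior_scope = c("global", "feature")) {
  stopifnot(inherits(result, "interaction_result"))
  prior_scope <- match.arg(prior_scope)
  if (result$n_replicates < 2)
    stop("need >= 2 replicates for testing")
  df <- result$n_replicates - 1
  feature_scale <- rep(1, length(result$features))
  if (identical(params, "estimate") && prior_scope == "global") {
    s2_std <- NULL
    for (fi in seq_along(result$features)) {
      mat <- matrix(result$pi[, , fi, ], ncol = result$n_replicates)
      s2 <- apply(mat[rowSums(is.na(mat)) == 0, , drop = FALSE], 1,
                  stats::var)
      m <- stats::median(s2, na.rm = TRUE)
      feature_scale[fi] <- if (is.finite(m) && m > 0) m else 1
      s2_std <- c(s2_std, s2 / feature_scale[fi])
    }
    fit <- fit_variance_prior(s2_std, df)
    params <- list(d0 = fit$d0, s02_std = fit$s02)
  }
  calls <- vector("list", length(result$features))
  for (fi in seq_along(result$features)) {
    f <- result$features[fi]
    mat <- result$pi[, , fi, , drop = FALSE]
    dim(mat) <- c(length(result$compounds) * length(result$lines),
                  result$n_replicates)
    units <- expand.grid(compound = result$compounds, line = result$lines,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ok <- rowSums(is.na(mat)) == 0
    fpar <- if (is.list(params) && !is.null(params$s02_std))
      list(d0 = params$d0, s02 = params$s02_std * feature_scale[fi])
    else params
    mt <- moderated_t_test(mat[ok, , drop = FALSE], params = fpar)
    df <- data.frame(compound = units$compound, line = units$line,
                     feature = f, role = unname(result$roles[units$compound]),
                     mean_pi = rowMeans(mat), t = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
    df$t[ok] <- mt$t
    df$p[ok] <- mt$p
    df$p_adj <- NA_real_
    df$p_adj[ok] <- bh_adjust(df$p[ok])
    calls[[fi]] <- df
  }
  calls <- do.call(rbind, calls)
  calls$significant <- !is.na(calls$p_adj) & calls$p_adj < fdr
  result$calls <- calls
  result$fdr <- fdr
  result
}

#' Summarise significant interaction calls
#'
#' @param result an \code{interaction_result} with calls (see
#'   \code{\link{test_interactions}}).
#' @param category_map named vector feature -> phenoprint category (default
#'   by name pattern).
#' @return list with \code{n_significant}, \code{per_line} (interactions per
#'   genetic background), \code{per_category_exclusive} (interactions whose
#'   (compound, line) pair is significant in exactly one category),
#'   \code{per_compound_breadth} (number of genetic backgrounds with >= 1
#'   interaction, per compound), and \code{calls} (significant rows).
#' @export
call_interactions <- function(result, category_map = NULL) {
  stopifnot(inherits(result, "interaction_result"), !is.null(result$calls))
  sig <- result$calls[result$calls$significant, , drop = FALSE]
  if (is.null(category_map))
    category_map <- default_category_map(result$features)
  per_line <- table(factor(sig$line, levels = result$lines))
  breadth <- tapply(sig$line, sig$compound, function(x) length(unique(x)))
  sig$category <- unname(category_map[sig$feature])
  if (nrow(sig) > 0) {
    pair_cat <- unique(sig[, c("compound", "line", "category")])
    n_cat_per_pair <- stats::aggregate(
      category ~ compound + line, data = pair_cat, FUN = length)
    excl_pairs <- n_cat_per_pair[n_cat_per_pair$category == 1,
                                 c("compound", "line")]
    excl <- merge(sig, excl_pairs, by = c("compound", "line"))
    per_cat_excl <- table(excl$category)
  } else {
    per_cat_excl <- table(character(0))
  }
  list(n_significant = nrow(sig),
       per_line = per_line,
       per_category_exclusive = per_cat_excl,
       per_compound_breadth = breadth,
       calls = sig)
}

#' Screen-level summary ratios from interaction counts
#'
#' Percentage summaries used when reporting a screen: significant
#' interactions over the number of testable (compound, line, feature) cells,
#' and compound hit fractions over the library size.
#'
#' @param n_significant number of significant interactions.
#' @param n_compounds,n_lines,n_features screen dimensions.
#' @param n_hit_compounds compounds with >= 1 interaction.
#' @param n_cellnumber_compounds compounds with >= 1 cell-number interaction.
#' @return named numeric vector of percentages (1 decimal).
#' @export
screen_summary_ratios <- function(n_significant, n_compounds, n_lines,
                                  n_features, n_hit_compounds,
                                  n_cellnumber_compounds = NA) {
  total <- n_compounds * n_lines * n_features
  round(c(
    pct_interactions = 100 * n_significant / total,
    pct_hit_compounds = 100 * n_hit_compounds / n_compounds,
    pct_cellnumber_compounds = 100 * n_cellnumber_compounds / n_compounds
  ), 1)
}
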
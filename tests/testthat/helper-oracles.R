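# Independent oracles used to cross-check package implementations.
# These deliberately share no code with the package internals.

# Alternating median subtraction, coded as a plain loop over the matrix.
oracle_median_polish <- function(M, tol = 1e-4, max_iter = 200) {
  resid <- M
  row_eff <- rep(0, nrow(M))
  col_eff <- rep(0, ncol(M))
  overall <- 0
  s_old <- 0
  for (it in seq_len(max_iter)) {
    for (i in seq_len(nrow(M))) {
      m <- stats::median(resid[i, ], na.rm = TRUE)
      resid[i, ] <- resid[i, ] - m
      row_eff[i] <- row_eff[i] + m
    }
    m <- stats::median(col_eff)
    col_eff <- col_eff - m
    overall <- overall + m
    for (j in seq_len(ncol(M))) {
      m <- stats::median(resid[, j], na.rm = TRUE)
      resid[, j] <- resid[, j] - m
      col_eff[j] <- col_eff[j] + m
    }
    m <- stats::median(row_eff)
    row_eff <- row_eff - m
    overall <- overall + m
    s_new <- sum(abs(resid), na.rm = TRUE)
    if (s_new == 0 || abs(s_new - s_old) < tol * s_new) break
    s_old <- s_new
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = resid)
}

# Naive O(n^3) complete-linkage agglomeration returning sorted merge heights.
oracle_complete_linkage_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_len(length(clusters) - 1)) {
      for (b in seq.int(a + 1, length(clusters))) {
        h <- max(D[clusters[[a]], clusters[[b]]])
        if (h < best[1]) best <- c(h, a, b)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# ECDF area over [-1, 1] by dense midpoint integration.
oracle_ecdf_auc <- function(x, n_grid = 2e5) {
  f <- stats::ecdf(x)
  grid <- seq(-1, 1, length.out = n_grid)
  mid <- (grid[-1] + grid[-n_grid]) / 2
  sum(f(mid)) * (2 / (n_grid - 1))
}

# One-sample moderated t via limma (independent route through squeezeVar).
oracle_moderated_t <- function(x) {
  testthat::skip_if_not_installed("limma")
  s2 <- apply(x, 1, stats::var)
  df <- ncol(x) - 1
  sq <- limma::squeezeVar(s2, df = df)
  t <- rowMeans(x) / sqrt(sq$var.post / ncol(x))
  list(t = t, p = 2 * stats::pt(-abs(t), df = sq$df.prior + df),
       d0 = sq$df.prior, s02 = sq$var.prior)
}

# Small full-screen simulation: design + tables + interaction pipeline.
run_screen <- function(n_compounds, n_lines, n_features, sigma, gamma_frac,
                       seed, gamma_range = c(0.5, 2), fdr = 0.01,
                       test = TRUE) {
  design <- gen_screen_design(n_compounds, n_lines, 2, 384, seed = seed)
  truth <- gen_ground_truth(design, n_features, sigma = sigma,
                            gamma_frac = gamma_frac,
                            gamma_range = gamma_range, seed = seed)
  ft <- gen_feature_tables(design, truth = truth, seed = seed)
  res <- estimate_interactions(ft$tables)
  if (test) res <- test_interactions(res, fdr = fdr)
  list(res = res, truth = truth)
}

planted_key <- function(truth) {
  idx <- which(truth$gamma != 0, arr.ind = TRUE)
  data.frame(compound = rownames(truth$gamma)[idx[, 1]],
             line = colnames(truth$gamma)[idx[, 2]],
             feature = dimnames(truth$gamma)[[3]][idx[, 3]],
             gamma = truth$gamma[idx], stringsAsFactors = FALSE)
}
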
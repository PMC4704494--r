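test_that("cell-number normalization maps the anchors to 0 and 1", {
  expect_equal(normalize_cell_number(3.2, negctrl_median = 7.1, kill_ref = 3.2), 0)
  expect_equal(normalize_cell_number(7.1, negctrl_median = 7.1, kill_ref = 3.2), 1)
  expect_equal(normalize_cell_number(5.15, 7.1, 3.2), 0.5)
  # values outside [0, 1] are allowed
  expect_lt(normalize_cell_number(2.0, 7.1, 3.2), 0)
  expect_error(normalize_cell_number(1, 2, 2), "degenerate")

  d <- gen_screen_design(5, 2, 2, 96, seed = 2)
  ft <- gen_feature_tables(d, n_features = 3, seed = 2)
  tb <- normalize_cell_feature(ft$tables)[[1]]
  for (cl in unique(tb$cell_line)) {
    neg <- tb$cell_number[tb$cell_line == cl & tb$role == "vehicle"]
    expect_equal(stats::median(neg), 1)
    kill <- tb$cell_number[tb$cell_line == cl & tb$role == "kill_reference"]
    expect_equal(stats::median(kill), 0)
  }
})

test_that("median polish matches the brute-force oracle and stats::medpolish", {
  # additive matrix: zero residuals
  r <- rnorm(6); c_ <- rnorm(9)
  M <- outer(r, c_, "+")
  mp <- median_polish(M)
  expect_lt(max(abs(mp$residuals)), 1e-12)

  # single spiked cell in a 4x4 zero matrix: medians are unmoved
  M2 <- matrix(0, 4, 4); M2[2, 3] <- 8
  mp2 <- median_polish(M2)
  expect_equal(mp2$residuals[2, 3], 8)
  expect_equal(mp2$overall, 0)
  expect_true(all(abs(c(mp2$row, mp2$col)) < 1e-12))

  set.seed(21)
  for (dims in list(c(5, 7), c(20, 9), c(50, 12))) {
    M3 <- matrix(rnorm(prod(dims)), dims[1])
    mine <- median_polish(M3, tol = 1e-8)
    orac <- oracle_median_polish(M3, tol = 1e-8)
    expect_lt(max(abs(mine$residuals - orac$residuals)), 1e-8)
    ref <- stats::medpolish(M3, eps = 1e-8, trace.iter = FALSE, maxiter = 200)
    expect_lt(max(abs(mine$residuals - ref$residuals)), 1e-8)
    # reconstruction identity
    recon <- mine$overall + outer(mine$row, mine$col, "+") + mine$residuals
    expect_lt(max(abs(M3 - recon)), 1e-9)
  }
  expect_error(median_polish(matrix(NA_real_, 2, 2)), "missing")
})

test_that("interaction coefficients absorb row/column shifts and recover plants", {
  set.seed(22)
  M <- matrix(rnorm(40), 8, 5)
  base <- median_polish(M, tol = 1e-10)$residuals
  # a whole-row shift is absorbed exactly by the first row-median sweep
  rshift <- M; rshift[3, ] <- rshift[3, ] + 2.5
  expect_equal(median_polish(rshift, tol = 1e-10)$residuals, base,
               tolerance = 1e-10)
  # a whole-column shift is absorbed up to the path dependence of the
  # alternating L1 iterate (the fit is not unique; residuals can move by a
  # few hundredths when the shifted element crosses a row median)
  cshift <- M; cshift[, 2] <- cshift[, 2] - 1.1
  expect_equal(median_polish(cshift, tol = 1e-10)$residuals, base,
               tolerance = 0.1)

  # noiseless screen, no interactions: all pi = 0
  out0 <- run_screen(10, 4, 5, sigma = 0, gamma_frac = 0, seed = 23,
                     test = FALSE)
  expect_lt(max(abs(out0$res$pi)), 1e-9)

  # single planted gamma = 2 at D = 20, L = 8, sigma = 0
  d <- gen_screen_design(20, 8, 2, 384, seed = 24)
  tr <- gen_ground_truth(d, 5, gamma_frac = 0, sigma = 0, seed = 24)
  tr$gamma["cpd_0007", "line_03", "dna.tex.01"] <- 2
  ft <- gen_feature_tables(d, truth = tr, seed = 24)
  res <- estimate_interactions(ft$tables)
  pm <- apply(res$pi, c(1, 2, 3), mean)
  expect_lt(abs(pm["cpd_0007", "line_03", "dna.tex.01"] - 2), 0.05)
  others <- pm[, , "dna.tex.01"]
  others["cpd_0007", "line_03"] <- 0
  expect_lt(max(abs(others)), 0.05)

  # permutation equivariance over compounds
  tb <- ft$tables
  perm <- lapply(tb, function(x) x[rev(seq_len(nrow(x))), ])
  res_p <- estimate_interactions(perm)
  expect_equal(res_p$pi[res$compounds, , , ], res$pi[res$compounds, , , ])
})

test_that("sign convention: genotype-specific growth defect gives negative pi", {
  d <- gen_screen_design(10, 4, 2, 96, seed = 25)
  tr <- gen_ground_truth(d, 2, gamma_frac = 0, sigma = 0, seed = 25)
  tr$gamma["cpd_0002", "line_04", "cell_number"] <- -1.2   # grows worse
  ft <- gen_feature_tables(d, truth = tr, seed = 25)
  res <- estimate_interactions(ft$tables)
  expect_lt(mean(res$pi["cpd_0002", "line_04", "cell_number", ]), -1)
})

test_that("moderated t matches the limma oracle and its closed-form limits", {
  skip_if_not_installed("limma")
  set.seed(26)
  n <- 2000; d0 <- 4; s02 <- 1; R <- 2
  truevar <- s02 * d0 / rchisq(n, d0)
  x <- matrix(rnorm(n * R, sd = sqrt(rep(truevar, R))), n, R)
  mt <- moderated_t_test(x)
  # hyperparameter recovery
  expect_lt(abs(mt$d0 - d0) / d0, 0.25)
  expect_lt(abs(mt$s02 - s02) / s02, 0.10)
  # agreement with the independent limma route
  orc <- oracle_moderated_t(x)
  expect_lt(max(abs(mt$t - orc$t)), 1e-6)
  expect_lt(max(abs(mt$p - orc$p)), 1e-6)
  expect_equal(mt$d0, orc$d0, tolerance = 1e-6)
  expect_equal(mt$s02, orc$s02, tolerance = 1e-6)
})

test_that("moderated t reduces to the ordinary t when the prior is a point", {
  set.seed(27)
  x <- matrix(rnorm(60, mean = 0.5), 20, 3)
  s2 <- apply(x, 1, var)
  # prior fixed at each unit's own variance with the shared value: use a
  # common variance so shrinkage cannot move it
  xc <- matrix(rnorm(40), 20, 2)
  xc <- t(apply(xc, 1, function(r) (r - mean(r)) / sd(r) * 0.7 + mean(r)))
  s2c <- apply(xc, 1, var)                    # all exactly 0.7^2
  expect_equal(max(s2c) - min(s2c), 0, tolerance = 1e-12)
  mt <- moderated_t_test(xc, params = list(d0 = 11, s02 = s2c[1]))
  tt <- rowMeans(xc) / sqrt(s2c / 2)
  expect_equal(mt$t, tt, tolerance = 1e-12)

  # a zero-variance unit among others still gets a finite statistic
  x2 <- rbind(c(1, 1), matrix(rnorm(30), 15, 2))
  mt2 <- moderated_t_test(x2)
  expect_true(is.finite(mt2$t[1]))
})

test_that("BH adjustment reproduces the step-up closed forms", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("interaction calls flag nothing under the flat null and summarise hits", {
  out <- run_screen(15, 4, 4, sigma = 0.2, gamma_frac = 0, seed = 28)
  res <- out$res
  res$calls$p[] <- 1; res$calls$p_adj[] <- 1
  res$calls$significant <- res$calls$p_adj < 0.01
  cc <- call_interactions(res)
  expect_equal(cc$n_significant, 0)

  # planted screen: summaries count planted structure
  d <- gen_screen_design(12, 4, 2, 96, seed = 29)
  tr <- gen_ground_truth(d, 4, gamma_frac = 0, sigma = 0.1, seed = 29)
  tr$gamma["cpd_0001", "line_01", "dna.int.01"] <- 2
  tr$gamma["cpd_0001", "line_02", "dna.int.01"] <- 2
  tr$gamma["cpd_0005", "line_03", "nuc.shape.01"] <- -2
  ft <- gen_feature_tables(d, truth = tr, seed = 29)
  res2 <- test_interactions(estimate_interactions(ft$tables), fdr = 0.01)
  cc2 <- call_interactions(res2)
  expect_gte(cc2$per_compound_breadth["cpd_0001"], 2)
  expect_true("cpd_0005" %in% names(cc2$per_compound_breadth))
})

test_that("null p-values are approximately uniform", {
  out <- run_screen(25, 10, 8, sigma = 0.25, gamma_frac = 0, seed = 30)
  p <- out$res$calls$p
  p <- p[!is.na(p)]
  expect_gt(length(p), 1500)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
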
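test_that("screen designs satisfy layout invariants and are deterministic", {
  d <- gen_screen_design(1, 1, 2, 384, seed = 1)
  expect_s3_class(d, "screen_design")
  expect_gte(sum(d$role == "sample"), 2)           # one well per replicate
  for (p in unique(d$plate)) {
    roles <- d$role[d$plate == p]
    expect_true(all(c("vehicle", "kill_reference") %in% roles))
  }
  d2 <- gen_screen_design(1, 1, 2, 384, seed = 1)
  expect_identical(d, d2)
  expect_false(identical(d, gen_screen_design(1, 1, 2, 384, seed = 2)))

  # full screen scale: all combinations covered, multi-plate auto-extension
  big <- gen_screen_design(1280, 12, 2, 384, seed = 1)
  samp <- big[big$role == "sample", ]
  combos <- unique(paste(samp$compound_id, samp$cell_line, samp$replicate))
  expect_equal(length(combos), 1280 * 12 * 2)
  expect_true(all(table(big$plate) <= 384))

  expect_error(gen_screen_design(10, 2, 2, 100), "plate_format")
  expect_error(gen_screen_design(10, 2, 1, 384), "n_replicates")
})

test_that("feature tables follow the additive model exactly when noiseless", {
  d <- gen_screen_design(6, 3, 2, 96, seed = 4)
  tr <- gen_ground_truth(d, 4, gamma_frac = 0, sigma = 0, seed = 4)
  ft <- gen_feature_tables(d, truth = tr, seed = 4)
  tb <- ft$tables$rep1
  feats <- feature_columns(tb)
  for (i in sample(nrow(tb), 20)) {
    di <- tb$compound_id[i]; ci <- tb$cell_line[i]
    expect_equal(unlist(tb[i, feats]),
                 tr$mu + tr$alpha[di, ] + tr$beta[ci, ],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # replicate tables identical to each other when noiseless and gamma = 0
  # (well layout is randomized per replicate, so align on compound x line)
  key <- function(tb) order(tb$compound_id, tb$cell_line)
  expect_equal(ft$tables$rep1[key(ft$tables$rep1), feats],
               ft$tables$rep2[key(ft$tables$rep2), feats],
               ignore_attr = TRUE)

  # a single planted interaction shifts exactly that well by gamma
  tr2 <- tr
  tr2$gamma["cpd_0003", "line_02", "dna.int.01"] <- 1.5
  ft2 <- gen_feature_tables(d, truth = tr2, seed = 4)
  delta <- ft2$tables$rep1$dna.int.01 - ft$tables$rep1$dna.int.01
  hit <- ft$tables$rep1$compound_id == "cpd_0003" &
    ft$tables$rep1$cell_line == "line_02"
  expect_equal(delta[hit], rep(1.5, sum(hit)))
  expect_equal(delta[!hit], rep(0, sum(!hit)))

  # determinism and truth always attached
  ft3 <- gen_feature_tables(d, truth = tr, seed = 4)
  expect_identical(ft$tables, ft3$tables)
  expect_s3_class(ft$truth, "ground_truth")
  expect_error(gen_ground_truth(d, 4, sigma = -1), "sigma")
})

test_that("well images carry their ground truth and respect packing", {
  img0 <- gen_well_images(0, seed = 1)
  expect_equal(nrow(img0$centers), 0)
  expect_lt(diff(range(img0$dna)), 1e-12)         # background only

  img <- gen_well_images(25, image_size = 400, seed = 2)
  expect_equal(nrow(img$centers), 25)
  # non-overlap by construction: pairwise center distance > 2 nuclear radii
  dmat <- as.matrix(dist(img$centers))
  expect_gt(min(dmat[upper.tri(dmat)]), 2 * img$params$nuclear_radius)

  # apoptotic-like (small nuclei) vs enlarged parameter sets
  small <- gen_well_images(10, nuclear_radius = 3, image_size = 300, seed = 3)
  large <- gen_well_images(10, nuclear_radius = 8, image_size = 300, seed = 3)
  expect_lt(mean(small$nuclear_radii), mean(large$nuclear_radii))

  expect_error(gen_well_images(500, image_size = 128, max_tries = 500),
               "packing")
})

test_that("well TIFF round-trips through a multi-page 16-bit file", {
  img <- gen_well_images(5, image_size = 128, seed = 9)
  path <- tempfile(fileext = ".tiff")
  write_well_tiff(img, path)
  back <- read_well_tiff(path)
  expect_lt(max(abs(back$dna - img$dna)), 1.6e-5)    # 16-bit quantization
  expect_lt(max(abs(back$actin - img$actin)), 1.6e-5)
  unlink(path)
})

test_that("combination grids reproduce the dose ladder and independence", {
  g <- gen_combination_grid(0.3, 0.4, synergy = 0, noise_sd = 0, seed = 1)
  doses <- sort(unique(g$dose_uM[g$arm == "A"]), decreasing = TRUE)
  expect_equal(doses, 10 / 2^(0:9))
  expect_equal(min(doses), 0.01953125, tolerance = 1e-9)
  # independence + zero noise: combination effect is exactly E_A + E_B
  b <- bliss_interaction(g)
  expect_equal(b$E_int, rep(0, nrow(b)), tolerance = 1e-12)
  expect_equal(b$E_AB, b$E_A + b$E_B, tolerance = 1e-12)

  g2 <- gen_combination_grid(hill_effect(1), hill_effect(2),
                             n_rep_single = 20, n_rep_combo = 10, seed = 2)
  expect_equal(sum(g2$arm == "A" & g2$dose_uM == 10), 20)
  expect_equal(sum(g2$arm == "AB" & g2$dose_uM == 10), 10)
  expect_error(gen_combination_grid(0.1, 0.1, dilution_factor = 1),
               "dilution_factor")
})

test_that("compound annotations give class-structured symmetric distances", {
  ann <- gen_compound_annotations(12, 3, structure_noise = 0, seed = 5)
  D <- ann$distances
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 12))
  expect_true(all(D >= 0 & D <= 1))
  same <- outer(ann$targets$target, ann$targets$target, "==")
  ut <- upper.tri(D)
  expect_lt(max(D[ut & same]), min(D[ut & !same]))

  # two classes, 4 compounds: 2 shared pairs, 4 non-shared
  a4 <- gen_compound_annotations(4, 2, seed = 1)
  cls <- classify_pairs(targets = a4$targets)
  expect_equal(sum(cls$class == "shared_selectivity"), 2)
  expect_equal(sum(cls$class == "no_shared_selectivity"), 4)
})

test_that("generators are bit-identical under a fixed seed", {
  expect_identical(gen_well_images(8, seed = 3), gen_well_images(8, seed = 3))
  expect_identical(gen_combination_grid(0.2, 0.3, seed = 3),
                   gen_combination_grid(0.2, 0.3, seed = 3))
  expect_identical(gen_compound_annotations(6, 2, seed = 3),
                   gen_compound_annotations(6, 2, seed = 3))
  expect_identical(gen_selection_tables(n_wells = 50, n_signal = 3,
                                        n_lincomb = 2, n_noise = 2, seed = 3),
                   gen_selection_tables(n_wells = 50, n_signal = 3,
                                        n_lincomb = 2, n_noise = 2, seed = 3))
})
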
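test_that("profile correlations match per-pair brute force and flag degeneracies", {
  set.seed(31)
  P <- matrix(rnorm(8 * 30), 8, 30,
              dimnames = list(sprintf("cpd_%04d", 1:8), NULL))
  C <- profile_correlations(P)
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 8))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(C[i, j], cor(P[i, ], P[j, ]))

  # duplicate and negated profiles
  P2 <- rbind(a = P[1, ], b = P[1, ], c = -P[1, ])
  C2 <- profile_correlations(P2)
  expect_equal(C2["a", "b"], 1)
  expect_equal(C2["a", "c"], -1)
  expect_equal(profile_distances(C2)["a", "b"], 0)
  expect_equal(profile_distances(C2)["a", "c"], 2)

  Pc <- rbind(P, flat = rep(1, 30))
  expect_warning(Cc <- profile_correlations(Pc), "constant")
  expect_true(all(is.na(Cc["flat", ])))
})

test_that("complete linkage follows forced merges and the brute-force oracle", {
  D <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- cluster_profiles(D)
  expect_equal(hc$height, c(0.1, 0.9))

  # duplicates merge first at height 0
  D2 <- as.matrix(dist(c(1, 1, 5, 9)))
  hc2 <- cluster_profiles(D2)
  expect_equal(hc2$height[1], 0)

  set.seed(32)
  X <- matrix(rnorm(12 * 6), 12)
  D3 <- as.matrix(dist(X))
  hc3 <- cluster_profiles(D3)
  expect_equal(hc3$height, oracle_complete_linkage_heights(D3),
               tolerance = 1e-12)
  expect_error(cluster_profiles(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("cluster extraction enforces the strict 3..9 size window", {
  # profiles: a pair, a 5-block, a 10-block, and loners, well separated
  set.seed(33)
  mk_block <- function(center, n, label)
    t(sapply(seq_len(n), function(i) center + rnorm(40, sd = 0.01))) |>
      (\(m) {rownames(m) <- paste0(label, seq_len(n)); m})()
  c1 <- rnorm(40); c2 <- rnorm(40); c3 <- rnorm(40)
  P <- rbind(mk_block(c1, 2, "pair"), mk_block(c2, 5, "five"),
             mk_block(c3, 10, "ten"))
  C <- profile_correlations(P)
  hc <- cluster_profiles(profile_distances(C))
  cl <- extract_clusters(hc, height_cut = 0.6, min_size = 3, max_size = 9)
  expect_equal(length(cl), 1)
  expect_setequal(cl[[1]], paste0("five", 1:5))
})

test_that("network construction applies the breadth and feature filters", {
  mk_call <- function(compound, line, feature, p = 1e-4)
    data.frame(compound = compound, line = line, feature = feature,
               role = "sample", p_adj = p, significant = TRUE)
  calls <- rbind(
    # broad compound: 4 genotypes -> excluded
    do.call(rbind, lapply(paste0("line_0", 1:4), function(l)
      mk_call("cpd_broad", l, "dna.int.01"))),
    # single-feature compound -> excluded
    mk_call("cpd_narrow", "line_01", "dna.int.01"),
    # keeper: 3 features across 2 genotypes -> 2 edges
    mk_call("cpd_keep", "line_01", "dna.int.01"),
    mk_call("cpd_keep", "line_01", "nuc.shape.01"),
    mk_call("cpd_keep", "line_02", "act.tex.01"),
    # control is removed regardless
    mk_call("vehicle", "line_01", "dna.int.01"))
  calls$role[calls$compound == "vehicle"] <- "vehicle"
  g <- build_network(calls, max_genotypes = 3, min_features = 2)
  expect_equal(sort(igraph::V(g)$name[igraph::V(g)$type == "compound"]),
               "cpd_keep")
  expect_equal(igraph::ecount(g), 2)
  expect_false("line_03" %in% igraph::V(g)$name)   # genotype without edges

  el <- export_network(g)
  expect_equal(nrow(el), 2)
})

test_that("pair classification respects the strict 0.6 structure boundary", {
  D <- matrix(c(0, 0.59, 0.60,
                0.59, 0, 0.80,
                0.60, 0.80, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  cls <- classify_pairs(distances = D, structure_cutoff = 0.6)
  get <- function(a, b) cls$class[cls$a == a & cls$b == b]
  expect_equal(get("x", "y"), "similar_structure")      # 0.59 < 0.6
  expect_equal(get("x", "z"), "different_structure")    # 0.60 not < 0.6
  expect_equal(get("y", "z"), "different_structure")

  tg <- data.frame(compound_id = c("x", "x", "y", "z"),
                   target = c("t1", "t2", "t2", "t3"))
  cls2 <- classify_pairs(targets = tg)
  expect_equal(cls2$class[cls2$a == "x" & cls2$b == "y"], "shared_selectivity")
  expect_equal(cls2$class[cls2$a == "x" & cls2$b == "z"],
               "no_shared_selectivity")

  # missing compound excluded with a reported count
  cls3 <- classify_pairs(compounds = c("x", "y", "ghost"), targets = tg)
  expect_equal(attr(cls3, "n_excluded"), 2)
})

test_that("ECDF area and the resolution index match oracles and closed forms", {
  # identical class distributions -> 0
  vals <- seq(-0.5, 0.5, length.out = 10)
  C <- diag(20); rownames(C) <- colnames(C) <- paste0("c", 1:20)
  cls <- data.frame(a = paste0("c", 1:10), b = paste0("c", 11:20),
                    class = rep(c("shared_selectivity", "no_shared_selectivity"),
                                each = 5))
  C[cbind(cls$a, cls$b)] <- rep(vals[1:5], 2)
  ri0 <- resolution_index(C, cls)
  expect_equal(ri0$delta_auc, 0)

  # separated point masses: maximum 2
  C2 <- C
  C2[cbind(cls$a[cls$class == "shared_selectivity"],
           cls$b[cls$class == "shared_selectivity"])] <- 1
  C2[cbind(cls$a[cls$class != "shared_selectivity"],
           cls$b[cls$class != "shared_selectivity"])] <- -1
  expect_equal(resolution_index(C2, cls)$delta_auc, 2)

  # oracle agreement and the closed-form mean-shift value
  set.seed(34)
  shared <- pmin(pmax(rnorm(200, 0.5, 0.1), -1), 1)
  nonshared <- pmin(pmax(rnorm(200, 0, 0.1), -1), 1)
  expect_equal(ecdf_auc(shared), oracle_ecdf_auc(shared), tolerance = 1e-5)
  expect_equal(ecdf_auc(shared), 1 - mean(shared), tolerance = 1e-9)
  delta <- ecdf_auc(nonshared) - ecdf_auc(shared)
  expect_equal(delta, 0.5, tolerance = 0.05)

  # shift invariance away from the boundaries (shift keeps all values in
  # (-1, 1) so no clipping occurs)
  expect_equal((ecdf_auc(nonshared - 0.2) - ecdf_auc(shared - 0.2)) - delta,
               0, tolerance = 1e-9)
})

test_that("profile views separate mode-of-action classes as expected", {
  ps <- gen_profile_set(seed = 35)
  tg <- data.frame(compound_id = names(ps$classes), target = ps$classes)
  cls <- classify_pairs(targets = tg)
  delta <- sapply(c("combined", "genotypes_only", "phenotypes_only"),
                  function(v) {
    P <- compound_profiles(ps$profiles, subset = v)
    resolution_index(profile_correlations(P), cls)$delta_auc
  })
  expect_gt(delta["combined"], delta["genotypes_only"])
  expect_gt(delta["combined"], delta["phenotypes_only"])
  expect_gt(delta["combined"], 0)
})

test_that("clustering is equivariant under compound relabelling", {
  set.seed(36)
  P <- matrix(rnorm(10 * 25), 10, 25,
              dimnames = list(sprintf("cpd_%02d", 1:10), NULL))
  D <- profile_distances(profile_correlations(P))
  hc <- cluster_profiles(D)
  perm <- sample(10)
  hc_p <- cluster_profiles(D[perm, perm])
  expect_equal(sort(hc$height), sort(hc_p$height), tolerance = 1e-12)
  cl <- extract_clusters(hc, height_cut = 1.2, min_size = 1, max_size = 10)
  cl_p <- extract_clusters(hc_p, height_cut = 1.2, min_size = 1, max_size = 10)
  norm <- function(x)
    unname(sort(sapply(x, function(v) paste(sort(v), collapse = "|"))))
  expect_equal(norm(cl), norm(cl_p))
})
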
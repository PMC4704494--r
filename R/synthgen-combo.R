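#' Generate a fixed-ratio drug combination grid
#'
#' Simulates plate-reader viability readouts for two single agents and their
#' fixed-ratio combination over a dilution series, plus plate positive
#' (full-kill) and negative (untreated) control wells. True per-dose effects
#' are retained as ground truth. Effects map to raw intensities on the log
#' scale: an effect of 0 sits at the negative-control level and an effect of
#' 1 at the positive-control level; Gaussian noise is added on the log scale.
#'
#' @param effect_A,effect_B single-agent effect models: either a function of
#'   dose or a numeric vector of per-dose effects (length \code{n_doses}).
#' @param synergy interaction bonus added to the combined effect
#'   (\code{E_AB = E_A + E_B + synergy}); positive values mean
#'   stronger-than-independent killing, i.e. a negative Bliss interaction
#'   term.
#' @param n_doses number of doses (default 10).
#' @param top_dose_uM top dose in micromolar (default 10).
#' @param dilution_factor serial dilution factor (> 1; default 2).
#' @param n_rep_single,n_rep_combo,n_rep_control replicate counts per dose for
#'   single agents, the combination, and each control.
#' @param noise_sd log-scale measurement noise standard deviation.
#' @param neg_raw,pos_raw raw intensity levels of the untreated and full-kill
#'   controls.
#' @param seed integer seed.
#' @return \code{data.frame} of class \code{combination_grid} in long format
#'   (\code{dose_uM}, \code{arm} in A/B/AB/pos/neg, \code{replicate},
#'   \code{raw_value}) with a \code{truth} attribute holding the per-dose true
#'   effects.
#' @export
gen_combination_grid <- function(effect_A, effect_B, synergy = 0,
                                 n_doses = 10, top_dose_uM = 10,
                                 dilution_factor = 2,
                                 n_rep_single = 20, n_rep_combo = 10,
                                 n_rep_control = 32,
                                 noise_sd = 0.05,
                                 neg_raw = 1000, pos_raw = 10, seed = 1L) {
  stopifnot(n_doses >= 1)
  if (dilution_factor <= 1) stop("dilution_factor must be > 1")
  doses <- top_dose_uM / dilution_factor^(seq_len(n_doses) - 1)
  eval_effect <- function(e) {
    if (is.function(e)) e(doses)
    else if (is.numeric(e) && length(e) %in% c(1L, n_doses)) rep_len(e, n_doses)
    else stop("effect model must be a function of dose or a vector of length 1 or n_doses")
  }
  EA <- eval_effect(effect_A)
  EB <- eval_effect(effect_B)
  EAB <- EA + EB + synergy

  lp <- log(pos_raw); ln <- log(neg_raw)
  raw_of <- function(E, n) exp(lp + (1 - E) * (ln - lp) +
                                 stats::rnorm(n, sd = noise_sd))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_doses)) {
    rows[[length(rows) + 1]] <- data.frame(
      dose_uM = doses[i], arm = "A", replicate = seq_len(n_rep_single),
      raw_value = raw_of(EA[i], n_rep_single))
    rows[[length(rows) + 1]] <- data.frame(
      dose_uM = doses[i], arm = "B", replicate = seq_len(n_rep_single),
      raw_value = raw_of(EB[i], n_rep_single))
    rows[[length(rows) + 1]] <- data.frame(
      dose_uM = doses[i], arm = "AB", replicate = seq_len(n_rep_combo),
      raw_value = raw_of(EAB[i], n_rep_combo))
  }
  rows[[length(rows) + 1]] <- data.frame(
    dose_uM = NA_real_, arm = "pos", replicate = seq_len(n_rep_control),
    raw_value = raw_of(1, n_rep_control))
  rows[[length(rows) + 1]] <- data.frame(
    dose_uM = NA_real_, arm = "neg", replicate = seq_len(n_rep_control),
    raw_value = raw_of(0, n_rep_control))
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  attr(grid, "truth") <- data.frame(dose_uM = doses, E_A = EA, E_B = EB,
                                    E_AB = EAB, E_int = -synergy)
  class(grid) <- c("combination_grid", "data.frame")
  grid
}

#' Hill-type single-agent effect model
#'
#' Convenience constructor for dose-response effect functions used with
#' \code{\link{gen_combination_grid}}: E(x) = Emax * x^h / (x^h + EC50^h).
#' @param ec50 half-maximal dose (same units as the dose ladder).
#' @param emax maximal effect.
#' @param hill Hill coefficient.
#' @return function of dose.
#' @export
hill_effect <- function(ec50, emax = 1, hill = 1) {
  function(x) emax * x^hill / (x^hill + ec50^hill)
}

#' Generate compound target annotations and a structural distance matrix
#'
#' Compounds are assigned to target-selectivity classes; the synthetic
#' pairwise chemical distance (a stand-in for a fingerprint-based Tanimoto
#' distance) is drawn so that within-class pairs sit around a small distance
#' and between-class pairs around a large one, with configurable overlap.
#'
#' @param n_compounds number of compounds.
#' @param n_target_classes number of selectivity classes (>= 1).
#' @param structure_noise half-width of the uniform jitter on distances; 0
#'   separates the classes perfectly.
#' @param d_within,d_between central distances of within-/between-class pairs.
#' @param seed integer seed.
#' @return list with \code{targets} (\code{data.frame}: compound_id, target)
#'   and \code{distances} (symmetric matrix in [0, 1] with zero diagonal).
#' @export
gen_compound_annotations <- function(n_compounds, n_target_classes,
                                     structure_noise = 0.1,
                                     d_within = 0.3, d_between = 0.8,
                                     seed = 1L) {
  stopifnot(n_compounds >= 1, n_target_classes >= 1)
  set.seed(seed)
  ids <- sprintf("cpd_%04d", seq_len(n_compounds))
  cls <- sprintf("target_%02d",
                 rep(seq_len(n_target_classes), length.out = n_compounds))
  D <- matrix(0, n_compounds, n_compounds, dimnames = list(ids, ids))
  if (n_compounds > 1) {
    for (i in seq_len(n_compounds - 1)) {
      for (j in seq.int(i + 1, n_compounds)) {
        base <- if (cls[i] == cls[j]) d_within else d_between
        d <- base + stats::runif(1, -structure_noise, structure_noise)
        D[i, j] <- D[j, i] <- min(max(d, 0), 1)
      }
    }
  }
  list(targets = data.frame(compound_id = ids, target = cls,
                            stringsAsFactors = FALSE),
       distances = D)
}

#' Generate class-structured interaction-profile tensors
#'
#' Emulates pooled interaction-coefficient tensors for compounds grouped into
#' mode-of-action classes, for benchmarking profile-similarity views. Each
#' class carries a rank-1 genotype x morphology interaction pattern that spans
#' every (line, feature) cell; compound-specific nuisance is confined to the
#' two marginal readouts (the cell-number row across lines and the
#' reference-line column across features), mimicking residual potency effects
#' that survive the two-way decomposition; i.i.d. noise covers all cells.
#'
#' @param n_classes number of mode-of-action classes.
#' @param class_size compounds per class.
#' @param n_lines,n_features tensor dimensions.
#' @param ref_line,cellnum_feature indices of the reference cell line and the
#'   cell-number feature.
#' @param class_sd scale of the class genotype/morphology vectors.
#' @param nuisance_sd scale of the compound-specific marginal nuisance.
#' @param noise_sd i.i.d. noise on every cell.
#' @param seed integer seed.
#' @return list with \code{profiles} (array compound x line x feature),
#'   \code{classes} (character vector per compound) and the index parameters.
#' @export
gen_profile_set <- function(n_classes = 10, class_size = 4,
                            n_lines = 12, n_features = 20,
                            ref_line = 1, cellnum_feature = 1,
                            class_sd = 1, nuisance_sd = 1, noise_sd = 0.5,
                            seed = 1L) {
  set.seed(seed)
  n_cpd <- n_classes * class_size
  ids <- sprintf("cpd_%04d", seq_len(n_cpd))
  lines <- sprintf("line_%02d", seq_len(n_lines))
  feats <- feature_names(n_features)
  classes <- rep(sprintf("class_%02d", seq_len(n_classes)), each = class_size)
  prof <- array(0, dim = c(n_cpd, n_lines, n_features),
                dimnames = list(ids, lines, feats))
  for (k in seq_len(n_classes)) {
    g <- stats::rnorm(n_lines, sd = class_sd)
    m <- stats::rnorm(n_features, sd = class_sd)
    S <- outer(g, m) / class_sd      # per-cell variance ~ class_sd^2
    for (d in which(classes == sprintf("class_%02d", k))) {
      P <- S
      P[, cellnum_feature] <- P[, cellnum_feature] +
        stats::rnorm(n_lines, sd = nuisance_sd)
      P[ref_line, ] <- P[ref_line, ] + stats::rnorm(n_features, sd = nuisance_sd)
      prof[d, , ] <- P + matrix(stats::rnorm(n_lines * n_features,
                                             sd = noise_sd), n_lines)
    }
  }
  list(profiles = prof, classes = stats::setNames(classes, ids),
       ref_line = ref_line, cellnum_feature = cellnum_feature)
}

#' Generate replicate feature tables for feature-selection benchmarks
#'
#' Builds two replicate well x feature matrices containing a known number of
#' independent replicate-correlated signal dimensions, plus features that are
#' linear combinations of those signals with added noise, plus pure-noise
#' features. Feature 1 ("cell_number") is the first signal. Signal features
#' carry less measurement noise than the linear combinations, so the stepwise
#' selection should recover exactly the signal set.
#'
#' @param n_wells number of wells.
#' @param n_signal number of orthogonal latent signals.
#' @param n_lincomb number of linear-combination features.
#' @param n_noise number of pure-noise features.
#' @param signal_noise_sd per-replicate measurement noise on signal features
#'   (latent signals have unit variance; 0.2 gives replicate correlation ~0.96).
#' @param lincomb_noise_sd per-replicate noise on linear-combination features.
#' @param noise_sd variance scale of pure-noise features.
#' @param seed integer seed.
#' @return list with matrices \code{rep1}, \code{rep2} (wells x features,
#'   named columns) and \code{signal_features}.
#' @export
gen_selection_tables <- function(n_wells = 500, n_signal = 20,
                                 n_lincomb = 40, n_noise = 40,
                                 signal_noise_sd = 0.2,
                                 lincomb_noise_sd = 0.3,
                                 noise_sd = 1, seed = 1L) {
  stopifnot(n_signal >= 1, n_wells > n_signal + 2)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_wells * n_signal), n_wells)      # latent signals
  A <- matrix(stats::rnorm(n_signal * n_lincomb), n_signal)   # mixing
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")                   # unit columns
  mix <- Z %*% A
  nm <- c("cell_number",
          if (n_signal > 1) sprintf("signal.%02d", seq_len(n_signal - 1)),
          if (n_lincomb > 0) sprintf("lincomb.%02d", seq_len(n_lincomb)),
          if (n_noise > 0) sprintf("noise.%02d", seq_len(n_noise)))
  one_rep <- function() {
    sig <- Z + matrix(stats::rnorm(length(Z), sd = signal_noise_sd), n_wells)
    # combinations of the measured signal features, so that regression on the
    # selected signals removes them exactly (residuals ~ own noise)
    lc <- if (n_lincomb > 0)
      sig %*% A + matrix(stats::rnorm(n_wells * n_lincomb,
                                      sd = lincomb_noise_sd), n_wells)
    pn <- if (n_noise > 0)
      matrix(stats::rnorm(n_wells * n_noise, sd = noise_sd), n_wells)
    m <- cbind(sig, lc, pn)
    colnames(m) <- nm
    m
  }
  list(rep1 = one_rep(), rep2 = one_rep(),
       signal_features = nm[seq_len(n_signal)])
}
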
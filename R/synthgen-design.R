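#' Generate a multi-plate screen design
#'
#' Lays out a compound screen across isogenic cell lines on 96- or 384-well
#' plates. Each (cell line, replicate) combination receives its own plate
#' series; compounds are placed once per series in a seeded random order, and
#' every plate carries spike-in control wells: vehicle (negative control), a
#' strong-kill reference compound used to anchor cell-number normalization,
#' and a pathway-inhibitor reference.
#'
#' @param n_compounds number of library compounds (>= 1).
#' @param n_lines number of isogenic cell lines (>= 1).
#' @param n_replicates number of biological replicates (>= 2).
#' @param plate_format wells per plate, 96 or 384.
#' @param conc_uM screening concentration in micromolar (single dose).
#' @param controls_per_plate named integer vector with elements
#'   \code{vehicle}, \code{kill_reference}, \code{pathway_reference}; the
#'   default scales with plate format.
#' @param seed integer seed; the layout is deterministic given the seed.
#'
#' @return A \code{data.frame} of class \code{screen_design} with one row per
#'   well and columns \code{plate}, \code{well}, \code{row}, \code{col},
#'   \code{compound_id}, \code{conc_uM}, \code{cell_line}, \code{replicate},
#'   \code{role} (one of \code{sample}, \code{vehicle}, \code{kill_reference},
#'   \code{pathway_reference}).
#' @export
gen_screen_design <- function(n_compounds, n_lines, n_replicates,
                              plate_format = 384, conc_uM = 5,
                              controls_per_plate = NULL, seed = 1L) {
  stopifnot(n_compounds >= 1, n_lines >= 1)
  if (n_replicates < 2)
    stop("n_replicates must be >= 2")
  if (!plate_format %in% c(96L, 384L))
    stop("plate_format must be 96 or 384")
  dims <- if (plate_format == 384L) c(16L, 24L) else c(8L, 12L)
  if (is.null(controls_per_plate)) {
    controls_per_plate <- if (plate_format == 384L)
      c(vehicle = 12L, kill_reference = 4L, pathway_reference = 4L)
    else
      c(vehicle = 6L, kill_reference = 2L, pathway_reference = 2L)
  }
  need <- c("vehicle", "kill_reference", "pathway_reference")
  if (!all(need %in% names(controls_per_plate)))
    stop("controls_per_plate must name vehicle, kill_reference, pathway_reference")
  n_ctrl <- sum(controls_per_plate[need])
  n_sample_per_plate <- plate_format - n_ctrl
  if (n_sample_per_plate < 1)
    stop("control wells leave no sample wells on the plate")

  compounds <- sprintf("cpd_%04d", seq_len(n_compounds))
  lines <- sprintf("line_%02d", seq_len(n_lines))
  n_plates_per_series <- ceiling(n_compounds / n_sample_per_plate)

  well_name <- function(r, c) paste0(LETTERS[r], sprintf("%02d", c))
  rows <- rep(seq_len(dims[1]), each = dims[2])
  cols <- rep(seq_len(dims[2]), times = dims[1])

  set.seed(seed)
  out <- vector("list", n_lines * n_replicates)
  k <- 0L
  for (li in seq_len(n_lines)) {
    for (ri in seq_len(n_replicates)) {
      # independent seeded shuffles: compound order within the series and
      # control well positions per plate
      cpd_order <- sample(compounds)
      series <- vector("list", n_plates_per_series)
      for (pi in seq_len(n_plates_per_series)) {
        idx <- seq.int((pi - 1L) * n_sample_per_plate + 1L,
                       min(pi * n_sample_per_plate, n_compounds))
        cpds <- cpd_order[idx]
        n_wells_used <- length(cpds) + n_ctrl
        pos <- sample(plate_format, n_wells_used)
        ctrl_roles <- rep(need, times = controls_per_plate[need])
        roles <- c(ctrl_roles, rep("sample", length(cpds)))
        ids <- c(ctrl_roles, cpds)
        series[[pi]] <- data.frame(
          plate = sprintf("%s_rep%d_p%02d", lines[li], ri, pi),
          well = well_name(rows[pos], cols[pos]),
          row = rows[pos], col = cols[pos],
          compound_id = ids,
          conc_uM = ifelse(roles == "vehicle", 0, conc_uM),
          cell_line = lines[li],
          replicate = ri,
          role = roles,
          stringsAsFactors = FALSE
        )
      }
      k <- k + 1L
      out[[k]] <- do.call(rbind, series)
    }
  }
  design <- do.call(rbind, out)
  rownames(design) <- NULL
  attr(design, "plate_format") <- plate_format
  attr(design, "compounds") <- compounds
  attr(design, "cell_lines") <- lines
  attr(design, "n_replicates") <- as.integer(n_replicates)
  class(design) <- c("screen_design", "data.frame")
  design
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf(
    "screen_design: %d wells, %d plates (%d-well), %d compounds x %d lines x %d replicates\n",
    nrow(x), length(unique(x$plate)), attr(x, "plate_format"),
    length(attr(x, "compounds")), length(attr(x, "cell_lines")),
    attr(x, "n_replicates")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Draw ground-truth effects for a synthetic screen
#'
#' Samples the additive model on the glog scale: a per-feature baseline,
#' compound effects, cell-line effects and a sparse compound x line x feature
#' interaction tensor. Control pseudo-compounds (vehicle, kill reference,
#' pathway reference) receive fixed effects: the vehicle has none, the kill
#' reference suppresses the cell-number feature strongly, the pathway
#' reference moderately.
#'
#' @param design a \code{screen_design}.
#' @param n_features number of features; feature 1 is cell number.
#' @param alpha_sd,beta_sd standard deviations of compound and line effects.
#' @param gamma_frac fraction of (compound, line, feature) cells carrying a
#'   planted interaction (default 0.02).
#' @param gamma_range magnitude range of planted interactions; signs random.
#' @param sigma per-well noise standard deviation (glog scale).
#' @param baseline baseline value for every feature (glog scale).
#' @param kill_effect cell-number effect of the kill-reference compound.
#' @param seed integer seed.
#' @return list of class \code{ground_truth} with elements \code{mu},
#'   \code{alpha} (compound x feature), \code{beta} (line x feature),
#'   \code{gamma} (compound x line x feature array), \code{sigma},
#'   \code{feature_names}, \code{seed}.
#' @export
gen_ground_truth <- function(design, n_features,
                             alpha_sd = 0.5, beta_sd = 0.5,
                             gamma_frac = 0.02, gamma_range = c(0.5, 2),
                             sigma = 0.2, baseline = 6,
                             kill_effect = -3, seed = 1L) {
  stopifnot(inherits(design, "screen_design"), n_features >= 1)
  if (sigma < 0) stop("sigma must be >= 0")
  if (gamma_frac < 0 || gamma_frac > 1) stop("gamma_frac must be in [0, 1]")
  compounds <- attr(design, "compounds")
  lines <- attr(design, "cell_lines")
  ctrl <- c("vehicle", "kill_reference", "pathway_reference")
  all_ids <- c(compounds, ctrl)
  feats <- feature_names(n_features)

  set.seed(seed)
  D <- length(all_ids); L <- length(lines); F <- n_features
  mu <- stats::setNames(rep(baseline, F), feats)
  alpha <- matrix(stats::rnorm(D * F, sd = alpha_sd), D, F,
                  dimnames = list(all_ids, feats))
  alpha[ctrl, ] <- 0
  alpha["kill_reference", 1] <- kill_effect
  alpha["pathway_reference", 1] <- kill_effect / 6
  beta <- matrix(stats::rnorm(L * F, sd = beta_sd), L, F,
                 dimnames = list(lines, feats))
  gamma <- array(0, dim = c(D, L, F), dimnames = list(all_ids, lines, feats))
  n_cells <- length(compounds) * L * F
  n_hit <- round(gamma_frac * n_cells)
  if (n_hit > 0) {
    # plant only on library compounds, never on controls
    cells <- arrayInd(sample(n_cells, n_hit), .dim = c(length(compounds), L, F))
    mag <- stats::runif(n_hit, gamma_range[1], gamma_range[2]) *
      sample(c(-1, 1), n_hit, replace = TRUE)
    for (i in seq_len(n_hit))
      gamma[cells[i, 1], cells[i, 2], cells[i, 3]] <- mag[i]
  }
  structure(list(mu = mu, alpha = alpha, beta = beta, gamma = gamma,
                 sigma = sigma, feature_names = feats, seed = seed),
            class = "ground_truth")
}

#' Default synthetic feature names grouped by phenoprint family
#'
#' Feature 1 is always \code{cell_number}; the rest cycle through the DNA
#' intensity/texture, nuclear shape, cell shape and actin intensity/texture
#' families so that the default phenoprint category map applies.
#' @param n_features number of names to generate.
#' @return character vector of unique feature names.
#' @export
feature_names <- function(n_features) {
  stopifnot(n_features >= 1)
  fams <- c("dna.int", "dna.tex", "nuc.shape", "cell.shape", "act.int", "act.tex")
  if (n_features == 1) return("cell_number")
  rest <- n_features - 1L
  fam <- rep(fams, length.out = rest)
  idx <- stats::ave(seq_len(rest), fam, FUN = seq_along)
  c("cell_number", sprintf("%s.%02d", fam, idx))
}

#' Generate well-level feature tables from a design and ground truth
#'
#' Values follow the additive model on the glog scale:
#' \code{mu_f + alpha_df + beta_cf + gamma_dcf + noise}, with i.i.d. Gaussian
#' noise of standard deviation \code{sigma}. Optionally a number of "bad"
#' wells (blank images: zero cell count and zero intensity readouts) are
#' injected for QC testing.
#'
#' @param design a \code{screen_design}.
#' @param truth a \code{ground_truth}, or \code{NULL} to draw one with
#'   \code{\link{gen_ground_truth}} defaults.
#' @param n_features number of features (ignored when \code{truth} given).
#' @param n_bad_wells number of blank wells to inject per replicate.
#' @param seed integer seed for the noise (and for \code{truth} if drawn here).
#' @return list with \code{tables} (one \code{data.frame} per replicate: the
#'   design annotation columns, a logical \code{qc_pass} placeholder column
#'   set to \code{NA}, then one column per feature) and \code{truth}.
#' @export
gen_feature_tables <- function(design, truth = NULL, n_features = 10,
                               n_bad_wells = 0, seed = 1L) {
  stopifnot(inherits(design, "screen_design"))
  if (is.null(truth))
    truth <- gen_ground_truth(design, n_features, seed = seed)
  if (truth$sigma < 0) stop("sigma must be >= 0")
  feats <- truth$feature_names
  reps <- sort(unique(design$replicate))
  set.seed(seed + 1L)
  tables <- lapply(reps, function(r) {
    d <- as.data.frame(design)[design$replicate == r, , drop = FALSE]
    di <- match(d$compound_id, rownames(truth$alpha))
    ci <- match(d$cell_line, rownames(truth$beta))
    vals <- sapply(seq_along(feats), function(f) {
      truth$mu[f] + truth$alpha[cbind(di, f)] + truth$beta[cbind(ci, f)] +
        truth$gamma[cbind(di, ci, f)]
    })
    if (truth$sigma > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), sd = truth$sigma),
                            nrow(vals), ncol(vals))
    colnames(vals) <- feats
    if (n_bad_wells > 0) {
      bad <- sample(nrow(d), n_bad_wells)
      vals[bad, ] <- 0
      intcols <- grepl("^(dna|act)\\.int", feats)
      vals[bad, intcols] <- 0
      vals[bad, "cell_number"] <- 0
      d$bad_injected <- seq_len(nrow(d)) %in% bad
    }
    cbind(d, qc_pass = NA, as.data.frame(vals))
  })
  names(tables) <- paste0("rep", reps)
  list(tables = tables, truth = truth)
}
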
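#' Normalized percentage inhibition and compound effect
#'
#' Plate-control-anchored normalization of plate-reader viability readouts.
#' Raw values are log-transformed first (natural log; the base cancels in the
#' ratio): NPI = (mean log pos - log x) / (mean log pos - mean log neg),
#' where the positive controls are full-kill wells and the negative controls
#' untreated wells. The compound effect is E = 1 - NPI, so a reading at the
#' positive-control level gives E = 1 and at the negative-control level
#' E = 0. Note the anchoring: NPI itself is 1 at the untreated control.
#'
#' @param raw raw plate-reader values (> 0).
#' @param pos_raw,neg_raw raw positive-/negative-control replicate values.
#' @return list with vectors \code{npi} and \code{effect}.
#' @export
normalized_inhibition <- function(raw, pos_raw, neg_raw) {
  if (any(c(raw, pos_raw, neg_raw) <= 0))
    stop("raw plate-reader values must be positive (log transform)")
  mp <- mean(log(pos_raw)); mn <- mean(log(neg_raw))
  if (mp == mn) stop("degenerate controls: positive and negative means equal")
  npi <- (mp - log(raw)) / (mp - mn)
  list(npi = npi, effect = 1 - npi)
}

#' Bliss-independence scoring of a drug combination grid
#'
#' Per dose, single-agent and combination effects are computed from the
#' plate controls; the Bliss interaction term is estimated by plugging the
#' means into E_AB = E_A + E_B - E_A:B, i.e.
#' E_A:B = mean(E_A) + mean(E_B) - mean(E_AB). Negative E_A:B means
#' stronger-than-independent (synergistic) killing. The null E_A:B = 0 is
#' tested per dose: by default a Welch two-sample t comparing the
#' combination-effect replicates against single-agent sums paired by
#' replicate index (i-th A with i-th B); \code{test = "one_sample"} instead
#' tests the combination replicates against the plug-in constant
#' mean(E_A) + mean(E_B).
#'
#' @param grid long-format \code{data.frame} with columns \code{dose_uM},
#'   \code{arm} (A/B/AB/pos/neg), \code{replicate}, \code{raw_value} (see
#'   \code{\link{gen_combination_grid}}).
#' @param test "paired_sums" (default) or "one_sample".
#' @param min_rep_single,min_rep_combo minimum replicates per dose; doses
#'   below the minima are skipped with a warning.
#' @return \code{data.frame} of class \code{bliss_result}, one row per dose:
#'   \code{dose_uM}, \code{E_A}, \code{E_B}, \code{E_AB}, \code{E_int},
#'   \code{t}, \code{p}, \code{n_AB}.
#' @export
bliss_interaction <- function(grid, test = c("paired_sums", "one_sample"),
                              min_rep_single = 2, min_rep_combo = 2) {
  test <- match.arg(test)
  need <- c("dose_uM", "arm", "replicate", "raw_value")
  stopifnot(all(need %in% names(grid)))
  pos <- grid$raw_value[grid$arm == "pos"]
  neg <- grid$raw_value[grid$arm == "neg"]
  if (!length(pos) || !length(neg)) stop("grid lacks pos/neg control wells")
  eff <- function(x) normalized_inhibition(x, pos, neg)$effect
  doses <- sort(unique(grid$dose_uM[grid$arm %in% c("A", "B", "AB")]),
                decreasing = TRUE)
  rows <- lapply(doses, function(d) {
    at <- grid$dose_uM == d & !is.na(grid$dose_uM)
    eA <- eff(grid$raw_value[at & grid$arm == "A"])
    eB <- eff(grid$raw_value[at & grid$arm == "B"])
    eAB <- eff(grid$raw_value[at & grid$arm == "AB"])
    if (length(eA) < min_rep_single || length(eB) < min_rep_single ||
        length(eAB) < min_rep_combo) {
      warning(sprintf("dose %g skipped: insufficient replicates", d))
      return(NULL)
    }
    e_int <- mean(eA) + mean(eB) - mean(eAB)
    if (test == "paired_sums") {
      k <- min(length(eA), length(eB))
      sums <- eA[seq_len(k)] + eB[seq_len(k)]
      degenerate <- stats::var(sums) == 0 && stats::var(eAB) == 0
      tt <- if (degenerate) {
        # noiseless measurements: the statistic is a limit
        list(statistic = if (e_int == 0) 0 else sign(e_int) * Inf,
             p.value = if (e_int == 0) 1 else 0)
      } else stats::t.test(sums, eAB, var.equal = FALSE)
    } else {
      if (stats::var(eAB) == 0) {
        tt <- list(statistic = if (e_int == 0) 0 else -sign(e_int) * Inf,
                   p.value = if (e_int == 0) 1 else 0)
      } else tt <- stats::t.test(eAB, mu = mean(eA) + mean(eB))
    }
    data.frame(dose_uM = d, E_A = mean(eA), E_B = mean(eB), E_AB = mean(eAB),
               E_int = e_int, t = unname(tt$statistic), p = tt$p.value,
               n_AB = length(eAB))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(dose_uM = numeric(0), E_A = numeric(0), E_B = numeric(0),
                  E_AB = numeric(0), E_int = numeric(0), t = numeric(0),
                  p = numeric(0), n_AB = integer(0))
  class(out) <- c("bliss_result", "data.frame")
  out
}

#' Viability-corrected proteasome inhibition (percent)
#'
#' 100 * (1 - (PT/PC) / (VT/VC)): the treated/control proteasome activity
#' ratio corrected for the treated/control viability ratio. Vehicle
#' treatment (PT = PC, VT = VC) gives 0%; complete inhibition (PT = 0) gives
#' 100%; proportional loss of activity and viability (pure cytotoxicity)
#' gives 0%.
#'
#' @param PT treated proteasome activity.
#' @param PC control (vehicle) proteasome activity (> 0).
#' @param VT treated viability (> 0).
#' @param VC control viability (> 0).
#' @return percent inhibition.
#' @export
proteasome_inhibition <- function(PT, PC, VT, VC) {
  if (any(PC <= 0) || any(VT <= 0) || any(VC <= 0))
    stop("PC, VT, VC must be positive")
  100 * (1 - (PT / PC) / (VT / VC))
}

#' One-sided one-sample t-test of percent-inhibition replicates
#'
#' Tests the alternative inhibition > 0. With zero variance the statistic is
#' reported as a limit (+/- Inf, or t = 0 with p = 0.5 when the mean is also
#' zero) with a warning.
#'
#' @param values replicate percent-inhibition values (>= 2).
#' @return list with \code{t}, \code{p} (one-sided), \code{df}, \code{mean}.
#' @export
proteasome_test <- function(values) {
  n <- length(values)
  if (n < 2) stop("need >= 2 replicates")
  m <- mean(values)
  s <- stats::sd(values)
  df <- n - 1
  if (s == 0) {
    warning("zero variance; reporting limiting t statistic")
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
    return(list(t = t, p = p, df = df, mean = m))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = stats::pt(t, df = df, lower.tail = FALSE), df = df,
       mean = m)
}
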
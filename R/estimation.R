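# Estimators for the developmental model: retraction rates from track
# lifetimes, generation rates from Poisson count snapshots, the synapse
# maturation constant from the accumulation slope, and assembly of a
# complete genotype parameter set.

#' Retraction rates from filopodial lifetimes
#'
#' Splits the uncensored filopodium tracks at the lifetime `cutoff`
#' (default 8 min) into short- and long-lived classes and estimates the
#' first-order retraction constants as inverse mean lifetimes:
#' `c2_sF = 1 / mean(lifetime < cutoff)`,
#' `c2_lF = 1 / mean(lifetime >= cutoff)`. Censored tracks (no death
#' time) are excluded, with their number reported.
#'
#' @param tracks data.frame with at least `t_birth_min` and
#'   `t_death_min` (NA = censored); an optional `class` column is
#'   ignored for the split, which is purely lifetime-based.
#' @param cutoff class boundary in minutes (> 0).
#' @return list with `c2_sF`, `c2_lF` (min^-1), per-class `n`, and
#'   `n_censored`.
#' @export
#' @examples
#' tr <- data.frame(t_birth_min = c(0, 0, 0), t_death_min = c(2, 2, 12))
#' estimate_retraction_rates(tr)$c2_sF   # 0.5
estimate_retraction_rates <- function(tracks, cutoff = 8) {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    stop("'cutoff' must be a positive number of minutes", call. = FALSE)
  }
  stopifnot(is.data.frame(tracks),
            all(c("t_birth_min", "t_death_min") %in% names(tracks)))
  cens <- is.na(tracks$t_death_min)
  life <- tracks$t_death_min[!cens] - tracks$t_birth_min[!cens]
  if (any(life < 0)) stop("negative lifetimes in track table", call. = FALSE)
  short <- life[life < cutoff]
  long <- life[life >= cutoff]
  if (length(short) == 0L) {
    stop("no uncensored tracks in the short-lived class (< ",
         cutoff, " min)", call. = FALSE)
  }
  if (length(long) == 0L) {
    stop("no uncensored tracks in the long-lived class (>= ",
         cutoff, " min)", call. = FALSE)
  }
  list(c2_sF = 1 / mean(short), c2_lF = 1 / mean(long),
       n_short = length(short), n_long = length(long),
       n_censored = sum(cens), cutoff = cutoff)
}

#' Mean count per time instance (Poisson rate)
#'
#' The maximum-likelihood estimate of the Poisson mean is the sample
#' mean of the per-snapshot counts; the index of dispersion
#' (variance / mean) is returned as a goodness-of-fit diagnostic
#' (about 1 for Poisson data).
#'
#' @param snapshots data.frame of count snapshots with a `t_min` column
#'   plus one column per category.
#' @param category name of the count column to average.
#' @return list with `lambda`, `dispersion`, `n`.
#' @export
estimate_lambda <- function(snapshots, category) {
  stopifnot(is.data.frame(snapshots), nrow(snapshots) >= 1L)
  if (!category %in% names(snapshots)) {
    stop("unknown snapshot category '", category, "'", call. = FALSE)
  }
  x <- snapshots[[category]]
  lam <- mean(x)
  disp <- if (length(x) > 1L && lam > 0) stats::var(x) / lam else NA_real_
  list(lambda = lam, dispersion = disp, n = length(x))
}

#' Generation rate from the stationary filopodium count
#'
#' In the stationary immigration-death regime the mean count equals
#' generation over retraction, so the generation constant is recovered
#' as `c1 = lambda * c2 / f_F`, with `f_F` the filopodial drive at the
#' reference stage.
#'
#' @param lambda_P60 mean count per time instance at the reference
#'   stage.
#' @param c2 retraction constant (min^-1).
#' @param f_F_P60 drive value at the reference stage; must be positive
#'   (the clamped printed polynomial is zero well before P60, in which
#'   case a drive built from per-stage counts must be supplied — see
#'   [filopodial_drive()]).
#' @return `c1` (min^-1).
#' @export
estimate_generation_rate <- function(lambda_P60, c2, f_F_P60) {
  if (!is.finite(f_F_P60) || f_F_P60 <= 0) {
    stop("f_F at the reference stage must be > 0; the clamped drive ",
         "polynomial evaluates to 0 here - supply a positive drive value ",
         "(e.g. from filopodial_drive())", call. = FALSE)
  }
  if (lambda_P60 < 0 || c2 < 0) {
    stop("'lambda_P60' and 'c2' must be >= 0", call. = FALSE)
  }
  lambda_P60 * c2 / f_F_P60
}

#' Synapse maturation constant from the accumulation slope
#'
#' `c6 = (delta_S / delta_t) / mean_synB`: the steepest increase of the
#' mean synapse count per terminal over one inter-stage interval,
#' divided by the mean number of stabilized synaptogenic bulbs. With
#' the published control inputs (5 synapses per 600 min at 1.1 bulbs)
#' this is 5/660 = 1/132 min^-1 exactly.
#'
#' @param delta_S synapse increment over the interval.
#' @param delta_t interval length (min, > 0).
#' @param mean_synB mean stabilized-bulb count (> 0).
#' @return `c6` (min^-1).
#' @export
#' @examples
#' estimate_c6(5, 600, 1.1)   # 1/132
estimate_c6 <- function(delta_S, delta_t, mean_synB) {
  if (!is.finite(delta_t) || delta_t <= 0 ||
      !is.finite(mean_synB) || mean_synB <= 0) {
    stop("'delta_t' and 'mean_synB' must be positive", call. = FALSE)
  }
  if (delta_S < 0) stop("'delta_S' must be >= 0", call. = FALSE)
  (delta_S / delta_t) / mean_synB
}

#' Steepest inter-stage synapse slope
#'
#' Given a per-stage table of mean synapse counts, returns the largest
#' increment between consecutive stages together with the interval
#' length in minutes — the inputs [estimate_c6()] expects.
#'
#' @param stage_table data.frame with columns `stage` (percent pupal
#'   development) and `synapses` (mean count per terminal).
#' @return list with `delta_S`, `delta_t` (min) and the `from`/`to`
#'   stages.
#' @export
steepest_synapse_slope <- function(stage_table) {
  stopifnot(is.data.frame(stage_table),
            all(c("stage", "synapses") %in% names(stage_table)),
            nrow(stage_table) >= 2L)
  o <- order(stage_table$stage)
  st <- stage_table$stage[o]; sy <- stage_table$synapses[o]
  dS <- diff(sy); dt <- diff(stage_to_min(st))
  k <- which.max(dS / dt)
  list(delta_S = dS[k], delta_t = dt[k], from = st[k], to = st[k + 1L])
}

#' Nonparametric bootstrap for lifetime and count estimators
#'
#' Resamples tracks (for the retraction rates) or snapshots (for the
#' Poisson mean) with replacement and returns percentile confidence
#' intervals.
#'
#' @param x track or snapshot data.frame.
#' @param statistic `"c2"` or `"lambda"`.
#' @param category snapshot column (for `"lambda"`).
#' @param cutoff lifetime class boundary (for `"c2"`).
#' @param B number of bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return list of percentile intervals per estimated quantity.
#' @export
bootstrap_estimate <- function(x, statistic = c("c2", "lambda"),
                               category = NULL, cutoff = 8,
                               B = 200L, level = 0.95, seed = 1L) {
  statistic <- match.arg(statistic)
  set.seed(as.integer(seed))
  alpha <- (1 - level) / 2
  if (statistic == "c2") {
    reps <- replicate(B, {
      xs <- x[sample.int(nrow(x), replace = TRUE), , drop = FALSE]
      est <- tryCatch(estimate_retraction_rates(xs, cutoff),
                      error = function(e) NULL)
      if (is.null(est)) c(NA_real_, NA_real_)
      else c(est$c2_sF, est$c2_lF)
    })
    list(c2_sF = stats::quantile(reps[1L, ], c(alpha, 1 - alpha),
                                 na.rm = TRUE),
         c2_lF = stats::quantile(reps[2L, ], c(alpha, 1 - alpha),
                                 na.rm = TRUE),
         B = B, level = level)
  } else {
    if (is.null(category)) stop("'category' required for lambda bootstrap",
                                call. = FALSE)
    reps <- replicate(B, {
      xs <- x[sample.int(nrow(x), replace = TRUE), , drop = FALSE]
      estimate_lambda(xs, category)$lambda
    })
    list(lambda = stats::quantile(reps, c(alpha, 1 - alpha)),
         B = B, level = level)
  }
}

#' Assemble a complete genotype parameter set from observations
#'
#' Runs the full estimation chain for one genotype: retraction
#' constants from track lifetimes, Poisson means from count snapshots,
#' generation constants from the stationary relation, the maturation
#' constant from the synapse-accumulation slope, the bulbous-tip
#' triple `(c5, B50, r3)` from the stationary KL fit ([fit_bulbs()]),
#' and finally `c3` from the rate factorization ([compute_c3()]).
#' `c4` stays fixed at the published 1/120 min^-1 unless overridden.
#' The procedure is deterministic given its inputs.
#'
#' @param tracks filopodium track table (see
#'   [estimate_retraction_rates()]).
#' @param snapshots count snapshot table with columns `t_min`, `sF`,
#'   `lF`.
#' @param bulb_obs optional list with probability (or frequency)
#'   vectors `sB` and `synB` on support `0..N`; when absent the triple
#'   is flagged unestimated.
#' @param synapse_slope optional list with `delta_S`, `delta_t`,
#'   `mean_synB` for [estimate_c6()] (or the output of
#'   [steepest_synapse_slope()] plus `mean_synB`).
#' @param f_F_P60 drive value at P60 used for the generation constants;
#'   default 1 (drive normalized at P60, as [filopodial_drive()] does).
#' @param fixed named list overriding `c4`, `t_half`, `poly_coeffs`.
#' @param genotype_label label stored in the result.
#' @param cutoff lifetime class boundary (min).
#' @param f1_mode feedback form, see [eval_f1()].
#' @return An object of class `"genotype_fit"`: a list with the
#'   assembled `params` ([dev_params()]), the per-stage `report`
#'   (which entries were fixed, estimated or unestimated) and all
#'   component estimates. `coef`, `print` and `summary` methods apply.
#' @export
estimate_genotype <- function(tracks, snapshots, bulb_obs = NULL,
                              synapse_slope = NULL, f_F_P60 = 1,
                              fixed = list(), genotype_label = "estimated",
                              cutoff = 8,
                              f1_mode = "inhibition") {
  c4 <- if (!is.null(fixed$c4)) fixed$c4 else 1 / 120
  t_half <- if (!is.null(fixed$t_half)) fixed$t_half else 1000
  poly_coeffs <- if (!is.null(fixed$poly_coeffs)) fixed$poly_coeffs
                 else printed_poly_coeffs()
  report <- list(c4 = "fixed, per published model",
                 t_half = "fixed, per published model")

  ret <- tryCatch(estimate_retraction_rates(tracks, cutoff),
                  error = function(e) {
                    stop("retraction-rate stage failed: ",
                         conditionMessage(e), call. = FALSE)
                  })
  lam_sF <- tryCatch(estimate_lambda(snapshots, "sF"),
                     error = function(e) {
                       stop("lambda stage failed (sF): ",
                            conditionMessage(e), call. = FALSE)
                     })
  lam_lF <- tryCatch(estimate_lambda(snapshots, "lF"),
                     error = function(e) {
                       stop("lambda stage failed (lF): ",
                            conditionMessage(e), call. = FALSE)
                     })
  c1_sF <- estimate_generation_rate(lam_sF$lambda, ret$c2_sF, f_F_P60)
  c1_lF <- estimate_generation_rate(lam_lF$lambda, ret$c2_lF, f_F_P60)
  report$c2 <- report$lambda <- report$c1 <- "estimated"

  c6 <- NA_real_
  if (!is.null(synapse_slope)) {
    c6 <- estimate_c6(synapse_slope$delta_S, synapse_slope$delta_t,
                      synapse_slope$mean_synB)
    report$c6 <- "estimated from accumulation slope"
  } else {
    c6 <- 5 / 660
    report$c6 <- "fixed, published control slope (5 per 600 min at 1.1 bulbs)"
  }

  bulb_fit <- NULL
  c5 <- B50 <- r3 <- NA_real_
  if (!is.null(bulb_obs)) {
    bulb_fit <- tryCatch(
      fit_bulbs(bulb_obs$sB, bulb_obs$synB, c4 = c4, c6 = c6,
                f1_mode = f1_mode),
      error = function(e) {
        stop("bulb-fit stage failed: ", conditionMessage(e), call. = FALSE)
      })
    co <- coef(bulb_fit)
    c5 <- co[["c5"]]; B50 <- co[["B50"]]; r3 <- co[["r3"]]
    report$bulb_triple <- "estimated by stationary KL fit"
  } else {
    report$bulb_triple <- "unestimated (no bulb observations)"
  }

  c3 <- NA_real_
  if (!is.null(bulb_obs)) {
    f_FB_P60 <- eval_f_FB(stage_to_min(60), t_half)
    c3 <- compute_c3(r3, lam_sF$lambda, lam_lF$lambda, f_FB_P60)
    report$c3 <- "derived from fitted r3"
  } else {
    report$c3 <- "unestimated"
  }

  params <- dev_params(
    genotype_label = genotype_label,
    c1_sF = c1_sF, c1_lF = c1_lF,
    c2_sF = ret$c2_sF, c2_lF = ret$c2_lF,
    c3 = if (is.na(c3)) 0 else c3,
    c4 = c4,
    c5 = if (is.na(c5)) 0 else c5,
    c6 = c6,
    B50 = if (is.na(B50)) 1 else B50,
    t_half = t_half, poly_coeffs = poly_coeffs, f1_mode = f1_mode)
  attr(params, "lambda_P60") <- c(sF = lam_sF$lambda, lF = lam_lF$lambda)

  structure(list(
    params = params,
    report = report,
    retraction = ret,
    lambda = list(sF = lam_sF, lF = lam_lF),
    bulb_fit = bulb_fit,
    r3 = r3,
    estimates = c(c1_sF = c1_sF, c1_lF = c1_lF,
                  c2_sF = ret$c2_sF, c2_lF = ret$c2_lF,
                  lambda_sF = lam_sF$lambda, lambda_lF = lam_lF$lambda,
                  c3 = c3, c4 = c4, c5 = c5, c6 = c6, B50 = B50, r3 = r3)),
    class = "genotype_fit")
}

#' @export
coef.genotype_fit <- function(object, ...) object$estimates

#' @export
print.genotype_fit <- function(x, ...) {
  cat("Genotype parameter estimation —",
      x$params$genotype_label, "\n")
  est <- x$estimates
  for (nm in names(est)) {
    cat(sprintf("  %-10s %s\n", nm,
                if (is.na(est[nm])) "(unestimated)"
                else formatC(est[nm], digits = 5, format = "g")))
  }
  invisible(x)
}

#' @export
summary.genotype_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.genotype_fit")
}

#' @export
print.summary.genotype_fit <- function(x, ...) {
  print(x$fit)
  cat("Provenance:\n")
  for (nm in names(x$fit$report)) {
    cat(sprintf("  %-12s %s\n", nm, x$fit$report[[nm]]))
  }
  if (!is.null(x$fit$bulb_fit)) {
    cat("Bulb fit diagnostics:\n")
    print(summary(x$fit$bulb_fit))
  }
  invisible(x)
}
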
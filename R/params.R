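#' Developmental-model parameter set
#'
#' Container for all rate constants and function coefficients of the
#' developmental (slow-timescale) model of one genotype: zero-order
#' generation and first-order retraction of short-lived (`sF`) and
#' long-lived (`lF`) filopodia, bulbous-tip formation, retraction,
#' stabilization and synapse maturation, plus the coefficients of the
#' slow modulation functions.
#'
#' Rates are in events per minute; model time is minutes after P40
#' (60 min per percent pupal development, so P60 is 1200 min and P100 is
#' 3600 min).
#'
#' @param genotype_label free-text genotype tag.
#' @param c1_sF,c1_lF zero-order generation constants (min^-1) for short-
#'   and long-lived filopodia; multiplied by the filopodial drive `f_F(t)`.
#' @param c2_sF,c2_lF first-order retraction constants (min^-1).
#' @param c3 bulb-formation constant (min^-1 per filopodium).
#' @param c4 transient-bulb retraction constant (min^-1); the published
#'   model fixes 1/120.
#' @param c5 bulb stabilization constant (min^-1).
#' @param c6 synapse maturation constant (min^-1).
#' @param B50 feedback half-saturation count for the synaptogenic-bulb
#'   auto-inhibition `f1`; must be positive.
#' @param t_half half-time (min) of the bulb-propensity switch `f_FB`.
#' @param poly_coeffs numeric vector of exactly six coefficients
#'   `p0..p5` of the fifth-order filopodial drive polynomial `f_F`
#'   (constant term first).
#' @param f1_mode `"inhibition"` (default) for the saturating form
#'   `B50/(synB + B50)`, or `"as_printed"` for the typeset
#'   `(synB + B50)/B50`. See [eval_f1()].
#'
#' @return An object of class `"dev_params"` (a validated named list).
#' @seealso [eval_f_F()], [eval_f_FB()], [eval_f1()], [propensities()],
#'   [genotype_presets()]
#' @export
#' @examples
#' p <- dev_params(c1_sF = 2, c2_sF = 1/3, c1_lF = 0.6, c2_lF = 1/15)
#' p$c4   # fixed published default, 1/120 min^-1
dev_params <- function(genotype_label = "unspecified",
                       c1_sF = 0, c1_lF = 0,
                       c2_sF = 0, c2_lF = 0,
                       c3 = 0,
                       c4 = 1 / 120,
                       c5 = 0,
                       c6 = 0,
                       B50 = 1,
                       t_half = 1000,
                       poly_coeffs = printed_poly_coeffs(),
                       f1_mode = c("inhibition", "as_printed")) {
  f1_mode <- match.arg(f1_mode)
  rates <- c(c1_sF = c1_sF, c1_lF = c1_lF, c2_sF = c2_sF, c2_lF = c2_lF,
             c3 = c3, c4 = c4, c5 = c5, c6 = c6)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(B50) || length(B50) != 1L || !is.finite(B50) || B50 <= 0) {
    stop("'B50' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(t_half) || length(t_half) != 1L || !is.finite(t_half) ||
      t_half <= 0) {
    stop("'t_half' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(poly_coeffs) || length(poly_coeffs) != 6L ||
      any(!is.finite(poly_coeffs))) {
    stop("'poly_coeffs' must be six finite coefficients p0..p5",
         call. = FALSE)
  }
  structure(
    list(genotype_label = as.character(genotype_label)[1L],
         c1_sF = c1_sF, c1_lF = c1_lF, c2_sF = c2_sF, c2_lF = c2_lF,
         c3 = c3, c4 = c4, c5 = c5, c6 = c6,
         B50 = B50, t_half = t_half,
         poly_coeffs = as.numeric(poly_coeffs),
         f1_mode = f1_mode),
    class = "dev_params"
  )
}

#' @export
print.dev_params <- function(x, ...) {
  cat("Developmental-model parameters —", x$genotype_label, "\n")
  cat(sprintf("  generation   c1_sF = %.4g  c1_lF = %.4g  (min^-1, x f_F(t))\n",
              x$c1_sF, x$c1_lF))
  cat(sprintf("  retraction   c2_sF = %.4g  c2_lF = %.4g  (min^-1)\n",
              x$c2_sF, x$c2_lF))
  cat(sprintf("  bulbous tips c3 = %.4g  c4 = %.4g  c5 = %.4g  (min^-1)\n",
              x$c3, x$c4, x$c5))
  cat(sprintf("  synapses     c6 = %.4g (min^-1)\n", x$c6))
  cat(sprintf("  feedback     B50 = %.4g (%s)   t_half = %g min\n",
              x$B50, x$f1_mode, x$t_half))
  cat("  f_F poly p0..p5:", format(x$poly_coeffs, digits = 3), "\n")
  invisible(x)
}

#' Printed coefficients of the filopodial drive polynomial
#'
#' The fifth-order polynomial coefficients (constant term first) that
#' downregulate filopodium generation on the slow developmental
#' timescale, exactly as published. Note that, taken at face value with
#' t in minutes, these coefficients drive the clamped polynomial to zero
#' for t above roughly 460 min; functions that must divide by
#' `f_F` therefore refuse a non-positive value, and the simulator
#' accepts an alternative drive built from per-stage filopodia counts
#' (see [filopodial_drive()]).
#'
#' @return numeric vector `c(p0, ..., p5)`.
#' @export
printed_poly_coeffs <- function() {
  c(1, -1.45e-3, 2.06e-6, -1.29e-9, 3.31e-13, -2.97e-14)
}

#' Convert a pupal stage to model time
#'
#' Model time runs in minutes after P40, at 60 min per percent pupal
#' development: `stage_to_min(60)` is 1200 and `stage_to_min(100)` is
#' 3600.
#'
#' @param stage percent pupal development (P40-P100 scale), numeric.
#' @return minutes after P40.
#' @export
#' @examples
#' stage_to_min(c(40, 60, 100))  # 0 1200 3600
stage_to_min <- function(stage) {
  stopifnot(is.numeric(stage), all(is.finite(stage)))
  if (any(stage < 40)) stop("pupal stage must be >= 40", call. = FALSE)
  (stage - 40) * 60
}

#' Developmental state of one axon terminal
#'
#' Integer copy numbers of the five species at a model time `t`
#' (minutes after P40): short-lived filopodia `sF`, long-lived
#' filopodia `lF`, transient bulbous tips `sB`, stabilized synaptogenic
#' bulbous tips `synB`, and synapses `S`.
#'
#' @param t model time, min after P40 (>= 0).
#' @param sF,lF,sB,synB,S non-negative integer counts.
#' @return An object of class `"dev_state"`.
#' @export
dev_state <- function(t = 0, sF = 0, lF = 0, sB = 0, synB = 0, S = 0) {
  counts <- c(sF = sF, lF = lF, sB = sB, synB = synB, S = S)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("state counts must be non-negative integers", call. = FALSE)
  }
  if (!is.finite(t) || t < 0) {
    stop("'t' must be a finite time >= 0 (minutes after P40)", call. = FALSE)
  }
  structure(list(t = t, sF = as.integer(sF), lF = as.integer(lF),
                 sB = as.integer(sB), synB = as.integer(synB),
                 S = as.integer(S)),
            class = "dev_state")
}

#' @export
print.dev_state <- function(x, ...) {
  cat(sprintf(
    "dev_state @ t = %g min: sF = %d, lF = %d, sB = %d, synB = %d, S = %d\n",
    x$t, x$sF, x$lF, x$sB, x$synB, x$S))
  invisible(x)
}

#' Built-in genotype presets
#'
#' Named list of complete [dev_params()] sets for the three modelled
#' conditions: `control` (wild type), `atg_mutant` (autophagy-deficient
#' atg6/atg7 photoreceptors) and `upregulated` (autophagy
#' upregulation). The shared constants are the published ones
#' (c4 = 1/120 min^-1, t_half = 1000 min, the printed drive-polynomial
#' coefficients, c6 from the steepest synapse-accumulation slope); the
#' genotype-specific live-imaging statistics behind the remaining
#' entries are not deposited, so those values are synthetic stand-ins
#' calibrated once so the stationary bulb counts fall in the reported
#' bands (one to two concurrent bulbous tips for control, three to four
#' for the autophagy mutants) and the control full-course simulation
#' accumulates 20-25 synapses by P90.
#'
#' Each preset also carries a `drive_table` attribute: per-stage mean
#' filopodia counts used to build the piecewise-linear filopodial drive
#' (see [filopodial_drive()]).
#'
#' @return named list of `dev_params` objects.
#' @export
#' @examples
#' genotype_presets()$control
genotype_presets <- function() {
  # shared, published constants
  c4 <- 1 / 120
  c6 <- 5 / (1.1 * 10 * 60)        # steepest Fig-type slope / mean bulbs
  # per-stage mean filopodia (synthetic fixed-timepoint counts); columns:
  # stage (percent pupal development), total filopodia
  drive_control <- data.frame(
    stage = c(40, 50, 60, 70, 80, 90, 100),
    filopodia = c(10, 14, 15, 14, 10, 5, 1))
  drive_atg <- data.frame(
    stage = c(40, 50, 60, 70, 80, 90, 100),
    filopodia = c(11, 16, 18, 17, 13, 7, 2))
  lam <- function(tab) tab$filopodia[tab$stage == 60]

  mk <- function(label, lambda_sF, lambda_lF, c2_sF, c2_lF, c3, c5, B50,
                 drive) {
    p <- dev_params(
      genotype_label = label,
      # drive is normalized to 1 at P60, so c1 = lambda * c2 there
      c1_sF = lambda_sF * c2_sF, c1_lF = lambda_lF * c2_lF,
      c2_sF = c2_sF, c2_lF = c2_lF,
      c3 = c3, c4 = c4, c5 = c5, c6 = c6, B50 = B50)
    attr(p, "drive_table") <- drive
    attr(p, "lambda_P60") <- c(sF = lambda_sF, lF = lambda_lF)
    p
  }

  # bulb-compartment triples (c3 via r3(P60), c5, B50) calibrated once so
  # the P60 stationary bulb means sit mid-band per genotype (see vignette)
  f_FB_P60 <- eval_f_FB(stage_to_min(60), 1000)
  list(
    control = mk("control",
                 lambda_sF = 6, lambda_lF = 9,
                 c2_sF = 1 / 3, c2_lF = 1 / 15,
                 c3 = 0.02183574 / (15 * f_FB_P60),
                 c5 = 0.03138528, B50 = 2,
                 drive = drive_control),
    atg_mutant = mk("atg_mutant",
                    lambda_sF = 7, lambda_lF = 11,
                    c2_sF = 1 / 3, c2_lF = 1 / 20,
                    c3 = 0.03919206 / (18 * f_FB_P60),
                    c5 = 0.04545455, B50 = 6,
                    drive = drive_atg),
    upregulated = mk("upregulated",
                     lambda_sF = 6, lambda_lF = 8,
                     c2_sF = 1 / 3, c2_lF = 1 / 12,
                     c3 = 0.00664037 / (14 * f_FB_P60),
                     c5 = 0.01262626, B50 = 8,
                     drive = drive_control)
  )
}
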
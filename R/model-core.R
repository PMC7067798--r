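#' Filopodial drive polynomial f_F(t)
#'
#' Evaluates the fifth-order polynomial that modulates filopodium
#' generation over developmental time, clamped at zero:
#' `f_F(t) = max(0, sum_i p_i t^i)`.
#'
#' @param t model time in minutes after P40 (>= 0); vectorized.
#' @param poly_coeffs six coefficients `p0..p5` (constant term first).
#' @return non-negative dimensionless scalar(s).
#' @export
#' @examples
#' eval_f_F(0)   # printed p0, i.e. 1
eval_f_F <- function(t, poly_coeffs = printed_poly_coeffs()) {
  if (length(poly_coeffs) != 6L || !is.numeric(poly_coeffs)) {
    stop("'poly_coeffs' must be six numeric coefficients p0..p5",
         call. = FALSE)
  }
  stopifnot(is.numeric(t), all(t >= 0))
  # Horner's scheme, highest order first
  acc <- rep(poly_coeffs[6L], length(t))
  for (k in 5:1) acc <- acc * t + poly_coeffs[k]
  pmax(0, acc)
}

#' Bulb-propensity switch f_FB(t)
#'
#' Sigmoidal (tanh) increase of the propensity to form bulbous tips over
#' developmental time:
#' `f_FB(t) = (1 + tanh((3/t_half) (t - t_half))) / 2`,
#' strictly increasing in `t` and bounded in (0, 1), with value 1/2 at
#' `t = t_half`.
#'
#' @param t model time (min after P40); vectorized.
#' @param t_half half-time in minutes (> 0); the published value is 1000.
#' @return scalar(s) in (0, 1).
#' @export
#' @examples
#' eval_f_FB(1000, 1000)  # 0.5
eval_f_FB <- function(t, t_half = 1000) {
  if (!is.numeric(t_half) || length(t_half) != 1L || !is.finite(t_half) ||
      t_half <= 0) {
    stop("'t_half' must be a single positive number", call. = FALSE)
  }
  0.5 * (1 + tanh((3 / t_half) * (t - t_half)))
}

#' Synaptogenic-bulb feedback f1(synB, B50)
#'
#' Feedback of the current number of stabilized synaptogenic bulbs on
#' the bulb-formation rate, modelling competition for limited synaptic
#' seeding factors. In the default `"inhibition"` mode this is the
#' saturating inhibition `B50 / (synB + B50)`, which decreases from 1
#' (no bulbs) towards 0 and equals 1/2 at `synB = B50`. The
#' `"as_printed"` mode evaluates the formula exactly as typeset in the
#' source model, `(synB + B50) / B50`, which instead increases with
#' `synB`; it is retained for comparison only.
#'
#' @param synB number of stabilized synaptogenic bulbs (>= 0); vectorized.
#' @param B50 half-saturation count (> 0).
#' @param f1_mode `"inhibition"` (default) or `"as_printed"`.
#' @return dimensionless scalar(s); in inhibition mode within (0, 1].
#' @export
#' @examples
#' eval_f1(0, 2)                 # 1 in either mode
#' eval_f1(2, 2)                 # 0.5
#' eval_f1(2, 2, "as_printed")   # 2
eval_f1 <- function(synB, B50, f1_mode = c("inhibition", "as_printed")) {
  f1_mode <- match.arg(f1_mode)
  if (!is.numeric(B50) || length(B50) != 1L || !is.finite(B50) || B50 <= 0) {
    stop("'B50' must be a single positive number", call. = FALSE)
  }
  stopifnot(is.numeric(synB), all(synB >= 0))
  if (f1_mode == "inhibition") B50 / (synB + B50) else (synB + B50) / B50
}

#' Reaction propensities of the developmental model
#'
#' Computes the eight reaction rates of the developmental model at a
#' given state and time:
#' \describe{
#'   \item{r1_sF, r1_lF}{zero-order generation of short-/long-lived
#'     filopodia, `f_F(t) * c1`;}
#'   \item{r2_sF, r2_lF}{first-order retraction, `count * c2`;}
#'   \item{r3}{bulbous-tip formation from any filopodium,
#'     `c3 * (sF + lF) * f1(synB, B50) * f_FB(t, t_half)`;}
#'   \item{r4}{transient-bulb retraction `c4 * sB` (the retracting bulb
#'     is not returned to the filopodium pool, per the model's stated
#'     simplification);}
#'   \item{r5}{bulb stabilization `c5 * sB`;}
#'   \item{r6}{synapse maturation `c6 * synB`.}
#' }
#'
#' @param state a [dev_state()].
#' @param params a [dev_params()].
#' @param drive optional filopodial drive function of `t` replacing
#'   `f_F` built from `params$poly_coeffs` (see [filopodial_drive()]).
#' @return named numeric vector of the eight propensities (min^-1).
#' @export
propensities <- function(state, params, drive = NULL) {
  stopifnot(inherits(state, "dev_state"), inherits(params, "dev_params"))
  counts <- c(state$sF, state$lF, state$sB, state$synB, state$S)
  if (any(counts < 0)) stop("invalid state: negative counts", call. = FALSE)
  fF <- if (is.null(drive)) eval_f_F(state$t, params$poly_coeffs)
        else drive(state$t)
  fFB <- eval_f_FB(state$t, params$t_half)
  f1 <- eval_f1(state$synB, params$B50, params$f1_mode)
  r <- c(
    r1_sF = fF * params$c1_sF,
    r2_sF = state$sF * params$c2_sF,
    r1_lF = fF * params$c1_lF,
    r2_lF = state$lF * params$c2_lF,
    r3    = params$c3 * (state$sF + state$lF) * f1 * fFB,
    r4    = params$c4 * state$sB,
    r5    = params$c5 * state$sB,
    r6    = params$c6 * state$synB
  )
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("propensities must be finite and >= 0", call. = FALSE)
  }
  r
}

#' Derive the bulb-formation constant c3
#'
#' Inverts the bulb-formation rate factorization at a reference time
#' (P60 in the published workflow):
#' `c3 = r3 / ((sF + lF) * f_FB)`.
#'
#' @param r3_P60 bulb-formation rate at the reference time (min^-1),
#'   with the feedback factor `f1` excluded (the fitted stationary
#'   birth-rate prefactor).
#' @param sF_P60,lF_P60 mean filopodium counts at the reference time.
#' @param f_FB_P60 value of the switch `f_FB` at the reference time (> 0).
#' @return `c3` in min^-1 per filopodium.
#' @export
#' @examples
#' compute_c3(0.1, 6, 4, 0.5)  # 0.02
compute_c3 <- function(r3_P60, sF_P60, lF_P60, f_FB_P60) {
  denom <- (sF_P60 + lF_P60) * f_FB_P60
  if (!is.finite(denom) || sF_P60 + lF_P60 <= 0 || f_FB_P60 <= 0) {
    stop("cannot derive c3: (sF + lF) and f_FB must both be positive",
         call. = FALSE)
  }
  if (r3_P60 < 0) stop("'r3_P60' must be >= 0", call. = FALSE)
  r3_P60 / denom
}

#' Piecewise-linear filopodial drive from per-stage counts
#'
#' Builds a replacement for the drive polynomial `f_F` by linear
#' interpolation of mean filopodia counts observed at fixed pupal
#' stages, normalized so the drive equals 1 at a reference stage
#' (default P60, where the generation constants are estimated). Outside
#' the supplied stage range the drive is held constant at the boundary
#' value.
#'
#' @param stage_table data.frame with columns `stage` (percent pupal
#'   development) and `filopodia` (mean count).
#' @param ref_stage stage at which the drive is 1 (default 60).
#' @return a function of model time `t` (min after P40).
#' @export
#' @examples
#' d <- filopodial_drive(data.frame(stage = c(40, 60, 80),
#'                                  filopodia = c(10, 15, 10)))
#' d(stage_to_min(60))  # 1
filopodial_drive <- function(stage_table, ref_stage = 60) {
  stopifnot(is.data.frame(stage_table),
            all(c("stage", "filopodia") %in% names(stage_table)))
  if (!ref_stage %in% stage_table$stage) {
    stop("'ref_stage' must be one of the tabulated stages", call. = FALSE)
  }
  ref <- stage_table$filopodia[stage_table$stage == ref_stage][1L]
  if (ref <= 0) stop("filopodia count at the reference stage must be > 0",
                     call. = FALSE)
  tt <- stage_to_min(stage_table$stage)
  yy <- stage_table$filopodia / ref
  function(t) stats::approx(tt, yy, xout = t, rule = 2)$y
}
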
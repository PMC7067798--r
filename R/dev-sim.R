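# Exact stochastic simulation of the developmental model.
#
# The generation reactions (and the bulb-formation reaction through f_FB)
# have time-dependent propensities, so the sampler is a thinning scheme:
# over a lookahead window the time-varying factors are bounded from above
# (f_FB is increasing, the drive is bounded on a fine grid), candidate
# event times are drawn at the bounding rate and accepted with probability
# true/bound. This is statistically exact for any bounded drive.

# stoichiometry: rows = reactions, cols = (sF, lF, sB, synB, S)
.DEV_STOICH <- matrix(c(
   1,  0,  0,  0, 0,   # R1_sF
  -1,  0,  0,  0, 0,   # R2_sF
   0,  1,  0,  0, 0,   # R1_lF
   0, -1,  0,  0, 0,   # R2_lF
   0,  0,  1,  0, 0,   # R3  (filopodium pool unchanged; see vignette)
   0,  0, -1,  0, 0,   # R4
   0,  0, -1,  1, 0,   # R5
   0,  0,  0, -1, 1    # R6
), nrow = 8, byrow = TRUE,
  dimnames = list(c("R1_sF", "R2_sF", "R1_lF", "R2_lF",
                    "R3", "R4", "R5", "R6"),
                  c("sF", "lF", "sB", "synB", "S")))

# max of the drive over [t0, t1]: endpoints plus a 1-min grid; both the
# clamped polynomial and piecewise-linear drives are resolved at this scale
.drive_max <- function(drive, t0, t1) {
  grid <- unique(c(t0, seq(t0, t1, by = 1), t1))
  # small inflation keeps this a true upper bound between grid points
  max(drive(grid)) * 1.001
}

#' Simulate the developmental model
#'
#' Draws one statistically exact realization of the time-inhomogeneous
#' Markov jump process with the propensities of [propensities()],
#' by rejection (thinning) sampling against per-window upper bounds of
#' the time-dependent factors, or alternatively by freezing the rates on
#' a 1-min grid (`method = "piecewise"`, kept for cross-validation).
#'
#' @param params a [dev_params()].
#' @param t_start,t_end simulation horizon in minutes after P40.
#' @param initial initial [dev_state()]; defaults to the all-zero state
#'   at `t_start`.
#' @param seed integer RNG seed; identical inputs and seed reproduce the
#'   trajectory exactly.
#' @param drive optional filopodial drive function of time replacing the
#'   clamped polynomial `f_F` (see [filopodial_drive()]); if `params`
#'   carries a `drive_table` attribute (as the presets do) it is used
#'   automatically.
#' @param lookahead thinning window length (min) over which the
#'   time-dependent factors are bounded.
#' @param method `"thinning"` (exact, default) or `"piecewise"`
#'   (1-min piecewise-constant rates).
#' @return An object of class `"dev_trajectory"`: a list with `times`,
#'   `reactions` (names as in the stoichiometry), `states` (matrix of
#'   post-event counts), `initial`, `params`, `seed`, `t_start`,
#'   `t_end`. If simulation stopped early because no reaction could ever
#'   fire again, attribute `"stopped_early"` carries the reason.
#' @export
#' @examples
#' p <- dev_params(c1_sF = 0.5, c2_sF = 0.25,
#'                 poly_coeffs = c(1, 0, 0, 0, 0, 0))
#' traj <- simulate_developmental(p, 0, 200, seed = 1)
#' traj
simulate_developmental <- function(params, t_start = 0, t_end,
                                   initial = NULL, seed = 1L,
                                   drive = NULL, lookahead = 10,
                                   method = c("thinning", "piecewise")) {
  stopifnot(inherits(params, "dev_params"))
  method <- match.arg(method)
  if (!(t_start < t_end)) stop("'t_start' must be < 't_end'", call. = FALSE)
  if (is.null(initial)) initial <- dev_state(t = t_start)
  stopifnot(inherits(initial, "dev_state"))
  if (is.null(drive) && !is.null(attr(params, "drive_table"))) {
    drive <- filopodial_drive(attr(params, "drive_table"))
  }
  if (is.null(drive)) {
    pc <- params$poly_coeffs
    drive <- function(t) eval_f_F(t, pc)
  }

  set.seed(as.integer(seed))
  x <- c(sF = initial$sF, lF = initial$lF, sB = initial$sB,
         synB = initial$synB, S = initial$S)
  t <- t_start
  c1s <- params$c1_sF; c1l <- params$c1_lF
  c2s <- params$c2_sF; c2l <- params$c2_lF
  c3 <- params$c3; c4 <- params$c4; c5 <- params$c5; c6 <- params$c6
  B50 <- params$B50; th <- params$t_half; f1m <- params$f1_mode
  f1v <- function(j) if (f1m == "inhibition") B50 / (j + B50)
                     else (j + B50) / B50

  cap <- 1024L
  ev_t <- numeric(cap); ev_r <- integer(cap)
  ev_x <- matrix(0L, cap, 5L)
  n_ev <- 0L
  stopped <- NULL

  rates_at <- function(tt, fF) {
    fFB <- 0.5 * (1 + tanh((3 / th) * (tt - th)))
    c(fF * c1s, x[1L] * c2s, fF * c1l, x[2L] * c2l,
      c3 * (x[1L] + x[2L]) * f1v(x[4L]) * fFB,
      c4 * x[3L], c5 * x[3L], c6 * x[4L])
  }
  push <- function(tt, ri) {
    n_ev <<- n_ev + 1L
    if (n_ev > cap) {
      cap <<- cap * 2L
      ev_t <<- c(ev_t, numeric(cap / 2L))
      ev_r <<- c(ev_r, integer(cap / 2L))
      ev_x <<- rbind(ev_x, matrix(0L, cap / 2L, 5L))
    }
    ev_t[n_ev] <<- tt; ev_r[n_ev] <<- ri; ev_x[n_ev, ] <<- x
  }

  if (method == "thinning") {
    while (t < t_end) {
      t1 <- min(t + lookahead, t_end)
      fF_max <- .drive_max(drive, t, t1)
      fFB_max <- 0.5 * (1 + tanh((3 / th) * (t1 - th)))
      # state is frozen between events, so state factors are exact
      b <- c(fF_max * c1s, x[1L] * c2s, fF_max * c1l, x[2L] * c2l,
             c3 * (x[1L] + x[2L]) * f1v(x[4L]) * fFB_max,
             c4 * x[3L], c5 * x[3L], c6 * x[4L])
      btot <- sum(b)
      if (btot <= 0) {
        # nothing can fire in this window; if no generation input exists
        # at all, nothing can ever fire again
        if (c1s == 0 && c1l == 0) {
          stopped <- "all propensities zero and none time-dependent"
          t <- t_end
          break
        }
        t <- t1
        next
      }
      tau <- stats::rexp(1L, btot)
      if (t + tau > t1) { t <- t1; next }
      t <- t + tau
      a <- rates_at(t, drive(t))
      u <- stats::runif(1L) * btot
      if (u <= sum(a)) {
        ri <- findInterval(u, cumsum(a), left.open = TRUE) + 1L
        x <- x + .DEV_STOICH[ri, ]
        push(t, ri)
      } # else thinning rejection: clock already advanced
    }
  } else {
    while (t < t_end) {
      t1 <- min(t + 1, t_end)
      a <- rates_at(t, drive(t))
      atot <- sum(a)
      if (atot <= 0) {
        if (c1s == 0 && c1l == 0) {
          stopped <- "all propensities zero and none time-dependent"
          t <- t_end
          break
        }
        t <- t1
        next
      }
      tau <- stats::rexp(1L, atot)
      if (t + tau > t1) { t <- t1; next }
      t <- t + tau
      ri <- findInterval(stats::runif(1L) * atot, cumsum(a),
                         left.open = TRUE) + 1L
      x <- x + .DEV_STOICH[ri, ]
      push(t, ri)
    }
  }

  states <- ev_x[seq_len(n_ev), , drop = FALSE]
  colnames(states) <- colnames(.DEV_STOICH)
  out <- structure(
    list(times = ev_t[seq_len(n_ev)],
         reactions = rownames(.DEV_STOICH)[ev_r[seq_len(n_ev)]],
         states = states,
         initial = initial, params = params, seed = as.integer(seed),
         t_start = t_start, t_end = t_end, method = method),
    class = "dev_trajectory")
  if (!is.null(stopped)) attr(out, "stopped_early") <- stopped
  out
}

#' @export
print.dev_trajectory <- function(x, ...) {
  fin <- final_state(x)
  cat(sprintf(
    "Developmental trajectory (%s), t in [%g, %g] min, %d events, seed %d\n",
    x$params$genotype_label, x$t_start, x$t_end, length(x$times), x$seed))
  cat(sprintf("  final state: sF = %d, lF = %d, sB = %d, synB = %d, S = %d\n",
              fin["sF"], fin["lF"], fin["sB"], fin["synB"], fin["S"]))
  if (!is.null(attr(x, "stopped_early"))) {
    cat("  stopped early:", attr(x, "stopped_early"), "\n")
  }
  invisible(x)
}

#' @export
summary.dev_trajectory <- function(object, ...) {
  tab <- table(factor(object$reactions, levels = rownames(.DEV_STOICH)))
  fin <- final_state(object)
  structure(list(events = tab, final = fin,
                 horizon = c(object$t_start, object$t_end)),
            class = "summary.dev_trajectory")
}

#' @export
print.summary.dev_trajectory <- function(x, ...) {
  cat("Event counts:\n"); print(x$events)
  cat("Final state:\n"); print(x$final)
  invisible(x)
}

#' @export
plot.dev_trajectory <- function(x, species = c("sF", "lF", "sB", "synB", "S"),
                                ...) {
  species <- match.arg(species, several.ok = TRUE)
  grid <- seq(x$t_start, x$t_end, length.out = 400L)
  snaps <- snapshot_counts(x, grid)
  ylim <- c(0, max(snaps[species], 1))
  graphics::plot(NA, xlim = range(grid), ylim = ylim,
                 xlab = "time (min after P40)", ylab = "copy number", ...)
  for (k in seq_along(species)) {
    graphics::lines(snaps$t_min, snaps[[species[k]]], col = k, lty = 1)
  }
  graphics::legend("topleft", legend = species, col = seq_along(species),
                   lty = 1, bty = "n")
  invisible(x)
}

final_state <- function(traj) {
  if (length(traj$times) == 0L) {
    ini <- traj$initial
    c(sF = ini$sF, lF = ini$lF, sB = ini$sB, synB = ini$synB, S = ini$S)
  } else {
    traj$states[nrow(traj$states), ]
  }
}

#' Sample a trajectory at fixed times
#'
#' Evaluates the piecewise-constant state of a trajectory at the
#' requested times using the right-continuous convention: a time that
#' coincides exactly with an event returns the post-event state.
#'
#' @param traj a `dev_trajectory`.
#' @param times numeric vector of times within the simulation horizon.
#' @return data.frame with columns `t_min, sF, lF, sB, synB, S`.
#' @export
snapshot_counts <- function(traj, times) {
  stopifnot(inherits(traj, "dev_trajectory"))
  if (any(times < traj$t_start | times > traj$t_end)) {
    stop("snapshot times must lie within the simulation horizon",
         call. = FALSE)
  }
  ini <- traj$initial
  x0 <- c(sF = ini$sF, lF = ini$lF, sB = ini$sB, synB = ini$synB, S = ini$S)
  idx <- findInterval(times, traj$times)           # right-continuous
  out <- matrix(0L, length(times), 5L,
                dimnames = list(NULL, names(x0)))
  for (k in seq_along(times)) {
    out[k, ] <- if (idx[k] == 0L) x0 else traj$states[idx[k], ]
  }
  data.frame(t_min = times, out)
}

#' Concurrent bulbous-tip statistics of a trajectory
#'
#' Summarizes the bulbous-tip compartment of a trajectory over an
#' observation window: the mean and empirical distribution of the
#' number of concurrently existing bulbous tips (`sB + synB`) sampled
#' at a fixed cadence, and per-bulb lifetimes. A bulb's life runs from
#' its R3 birth to either its R4 retraction or — if it stabilizes via
#' R5 — its R6 maturation into a synapse; bulbs still alive at the
#' window end are flagged censored. Bulbs observed for longer than
#' `stable_min` minutes count as stable (synaptogenic), censored ones
#' included when their observed span already exceeds the threshold.
#'
#' Individual bulbs are statistically exchangeable (memoryless
#' per-bulb hazards), so when a removal event fires the removed
#' individual is drawn uniformly from the live set with an auxiliary
#' RNG stream derived from the trajectory seed; results are
#' reproducible for a fixed trajectory.
#'
#' @param traj a `dev_trajectory`.
#' @param window length-2 numeric, observation window (min) within the
#'   horizon.
#' @param stable_min persistence threshold (min) for calling a bulb
#'   stable; default 40.
#' @param cadence sampling interval (min) for the concurrent counts.
#' @return An object of class `"bulb_stats"`: list with
#'   `mean_concurrent`, `count_distribution` (named proportions of
#'   `sB + synB`), `lifetimes` (data.frame: birth, end, lifetime,
#'   censored, stable), `fraction_stable`, `window`.
#' @export
concurrent_bulb_stats <- function(traj, window = c(traj$t_start, traj$t_end),
                                  stable_min = 40, cadence = 1) {
  stopifnot(inherits(traj, "dev_trajectory"), length(window) == 2L)
  if (!(window[1] < window[2]) ||
      window[1] < traj$t_start || window[2] > traj$t_end) {
    stop("'window' must be a non-empty interval within the horizon",
         call. = FALSE)
  }
  grid <- seq(window[1], window[2], by = cadence)
  snaps <- snapshot_counts(traj, grid)
  conc <- snaps$sB + snaps$synB

  # replay bulb identities; auxiliary stream so trajectory RNG is untouched
  aux <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(traj$seed + 10007L)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    sample.int(.Machine$integer.max, 1L)
  })
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(aux)

  live_sB <- numeric(0)   # birth times, names = id
  live_synB <- numeric(0)
  next_id <- 1L
  births <- ends <- numeric(0); cens <- logical(0)
  rel <- which(traj$times >= window[1] & traj$times <= window[2])
  for (k in rel) {
    r <- traj$reactions[k]; tt <- traj$times[k]
    if (r == "R3") {
      live_sB <- c(live_sB, stats::setNames(tt, next_id))
      next_id <- next_id + 1L
    } else if (r == "R4" && length(live_sB) > 0L) {
      j <- if (length(live_sB) == 1L) 1L else sample.int(length(live_sB), 1L)
      births <- c(births, live_sB[j]); ends <- c(ends, tt)
      cens <- c(cens, FALSE)
      live_sB <- live_sB[-j]
    } else if (r == "R5" && length(live_sB) > 0L) {
      j <- if (length(live_sB) == 1L) 1L else sample.int(length(live_sB), 1L)
      live_synB <- c(live_synB, live_sB[j])
      live_sB <- live_sB[-j]
    } else if (r == "R6" && length(live_synB) > 0L) {
      j <- if (length(live_synB) == 1L) 1L
           else sample.int(length(live_synB), 1L)
      births <- c(births, live_synB[j]); ends <- c(ends, tt)
      cens <- c(cens, FALSE)
      live_synB <- live_synB[-j]
    }
  }
  for (b in c(live_sB, live_synB)) {
    births <- c(births, b); ends <- c(ends, window[2]); cens <- c(cens, TRUE)
  }
  lt <- data.frame(birth = births, end = ends,
                   lifetime = ends - births, censored = cens)
  lt$stable <- lt$lifetime > stable_min
  frac_stable <- if (nrow(lt) > 0) mean(lt$stable) else NA_real_

  structure(list(
    mean_concurrent = mean(conc),
    count_distribution = proportions(table(conc)),
    lifetimes = lt,
    fraction_stable = frac_stable,
    stable_min = stable_min,
    window = window),
    class = "bulb_stats")
}

#' @export
print.bulb_stats <- function(x, ...) {
  cat(sprintf("Bulbous-tip statistics over [%g, %g] min\n",
              x$window[1], x$window[2]))
  cat(sprintf("  mean concurrent bulbs: %.3f\n", x$mean_concurrent))
  cat(sprintf("  bulbs observed: %d (%.0f%% persisting > %g min)\n",
              nrow(x$lifetimes), 100 * x$fraction_stable, x$stable_min))
  invisible(x)
}

#' Export a trajectory as a tidy table
#'
#' @param traj a `dev_trajectory`.
#' @return data.frame with one row per event: `time, reaction, sF, lF,
#'   sB, synB, S`.
#' @export
trajectory_table <- function(traj) {
  stopifnot(inherits(traj, "dev_trajectory"))
  data.frame(time = traj$times, reaction = traj$reactions,
             traj$states, row.names = NULL)
}
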
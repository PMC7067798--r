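# Winner-takes-all seed-pool model: filopodia compete for a conserved
# pool of synaptic seeding factors. A filopodium holding i seeds gains
# seeds at rate S*c_in, releases them at c_out, and retracts at 1/i
# (competitive advantage) or at a constant (autophagy-upregulation
# variant); retraction returns all held seeds to the pool.

#' Mechanistic (winner-takes-all) model parameters
#'
#' @param n number of seed states per filopodium (cap on seeds held);
#'   default 120.
#' @param c_in per-seed accumulation constant (time^-1), default 0.07;
#'   a filopodium with spare capacity gains a seed at rate
#'   `S * c_in` where `S` is the free pool.
#' @param c_out release constant (time^-1), default 1.5.
#' @param g1 filopodium emergence rate (time^-1); the published choice
#'   is the control transient-bulb emergence rate at P60.
#' @param mode `"competitive"` (retraction hazard `1/i`, the
#'   winner-takes-all rule) or `"upregulated"` (constant hazard,
#'   modelling loss of the competitive advantage under autophagy
#'   upregulation).
#' @param upregulated_const retraction constant for `"upregulated"`
#'   mode; the published choice equals `c4 = 1/120`.
#' @param mean_bulbs_P60 genotype-specific mean bulbous-tip count used
#'   to initialize the pool, `S(t0) = round(n * mean_bulbs_P60)`
#'   (round half up).
#' @param bulb_threshold seeds required for a filopodium to count as a
#'   bulbous tip; default `ceiling(n / 4)`.
#' @param seed_return if `FALSE`, retraction destroys the held seeds
#'   instead of returning them to the pool (sensitivity variant; breaks
#'   resource conservation by construction).
#' @return An object of class `"mech_params"`.
#' @export
mech_params <- function(n = 120L, c_in = 0.07, c_out = 1.5,
                        g1 = 0.0218,
                        mode = c("competitive", "upregulated"),
                        upregulated_const = 1 / 120,
                        mean_bulbs_P60 = 1.1,
                        bulb_threshold = ceiling(n / 4),
                        seed_return = TRUE) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (n < 4L) stop("'n' must be >= 4", call. = FALSE)
  rates <- c(c_out = c_out, g1 = g1,
             upregulated_const = upregulated_const)
  if (any(!is.finite(rates)) || any(rates <= 0) ||
      !is.finite(c_in) || c_in < 0) {
    stop("rates must be finite and positive (c_in may be 0)",
         call. = FALSE)
  }
  if (bulb_threshold < 1L || bulb_threshold > n) {
    stop("'bulb_threshold' must lie in [1, n]", call. = FALSE)
  }
  structure(list(n = n, c_in = c_in, c_out = c_out, g1 = g1, mode = mode,
                 upregulated_const = upregulated_const,
                 mean_bulbs_P60 = mean_bulbs_P60,
                 bulb_threshold = as.integer(bulb_threshold),
                 seed_return = isTRUE(seed_return)),
            class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat(sprintf(
    "Winner-takes-all parameters: n = %d, c_in = %g, c_out = %g, g1 = %g\n",
    x$n, x$c_in, x$c_out, x$g1))
  cat(sprintf("  mode = %s%s, pool init from mean bulbs %.3g, threshold %d\n",
              x$mode,
              if (x$mode == "upregulated")
                sprintf(" (const = %g)", x$upregulated_const) else "",
              x$mean_bulbs_P60, x$bulb_threshold))
  invisible(x)
}

#' Initial seed-pool size
#'
#' `S(t0) = round(n * mean_bulbs_P60)` with round-half-up ("next
#' integer") convention: 120 * 1.1 gives exactly 132.
#'
#' @param n number of seed states.
#' @param mean_bulbs_P60 genotype-specific mean bulbous-tip count
#'   (> 0).
#' @return integer pool size.
#' @export
#' @examples
#' init_pool(120, 1.1)   # 132
init_pool <- function(n, mean_bulbs_P60) {
  if (!is.finite(n) || n <= 0 || !is.finite(mean_bulbs_P60) ||
      mean_bulbs_P60 <= 0) {
    stop("'n' and 'mean_bulbs_P60' must be positive", call. = FALSE)
  }
  as.integer(floor(n * mean_bulbs_P60 + 0.5))
}

#' Per-reaction propensities of the mechanistic model
#'
#' Emergence fires at `g1`. Per live filopodium with `i` seeds:
#' accumulation at `S * c_in` (blocked at the cap `i = n`), release at
#' `c_out` if `i > 0`, retraction at `1 / max(i, 1)` in competitive
#' mode or at the constant `upregulated_const` in upregulated mode.
#'
#' @param pool free seed count.
#' @param seeds integer vector of per-filopodium seed counts.
#' @param params a [mech_params()].
#' @return list with scalar `emergence` and per-filopodium vectors
#'   `accumulate`, `release`, `retract`.
#' @export
mech_propensities <- function(pool, seeds, params) {
  stopifnot(inherits(params, "mech_params"), pool >= 0, all(seeds >= 0),
            all(seeds <= params$n))
  acc <- ifelse(seeds < params$n, pool * params$c_in, 0)
  rel <- ifelse(seeds > 0, params$c_out, 0)
  ret <- if (params$mode == "competitive") 1 / pmax(seeds, 1)
         else rep(params$upregulated_const, length(seeds))
  list(emergence = params$g1, accumulate = acc, release = rel,
       retract = ret)
}

#' Simulate the winner-takes-all seed-pool model
#'
#' Runs the four-reaction competition model for a fixed number of
#' stochastic simulation steps (one Gillespie event per step), with
#' exponential waiting times tracked so that lifetimes are measured in
#' model time. Seeds are conserved exactly: accumulation moves one seed
#' pool-to-filopodium, release the reverse, and retraction returns all
#' held seeds to the pool (unless `seed_return = FALSE`).
#'
#' @param params a [mech_params()].
#' @param steps number of reaction events (default 100000).
#' @param seed RNG seed.
#' @return An object of class `"mech_history"`: list with per-step
#'   vectors `time`, `event` (factor: emergence/accumulate/release/
#'   retract), `pool`, `n_filopodia`, `n_bulbs`, an `event_log`
#'   data.frame (`time`, `event`, `filo_id`, `seeds_after`) for episode
#'   reconstruction, the `params`, `seed` and initial pool.
#' @export
simulate_mechanistic <- function(params, steps = 100000L, seed = 1L) {
  stopifnot(inherits(params, "mech_params"))
  steps <- as.integer(steps)
  if (steps < 2L) stop("'steps' must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))

  n <- params$n; c_in <- params$c_in; c_out <- params$c_out
  g1 <- params$g1; competitive <- params$mode == "competitive"
  rconst <- params$upregulated_const
  pool0 <- init_pool(n, params$mean_bulbs_P60)
  pool <- pool0
  ids <- integer(0); seeds <- integer(0)
  next_id <- 1L
  total0 <- pool0

  time <- numeric(steps); event <- integer(steps)
  pool_v <- integer(steps); nfil <- integer(steps); nbul <- integer(steps)
  log_id <- integer(steps); log_i <- integer(steps)
  t <- 0
  thr <- params$bulb_threshold
  ev_names <- c("emergence", "accumulate", "release", "retract")

  for (s in seq_len(steps)) {
    k <- length(seeds)
    acc <- if (k) ifelse(seeds < n, pool * c_in, 0) else numeric(0)
    rel <- if (k) ifelse(seeds > 0, c_out, 0) else numeric(0)
    ret <- if (k) {
      if (competitive) 1 / pmax(seeds, 1) else rep(rconst, k)
    } else numeric(0)
    a <- c(g1, acc, rel, ret)
    atot <- sum(a)
    stopifnot(atot > 0)     # g1 > 0 always, so this cannot trip
    t <- t + stats::rexp(1L, atot)
    u <- stats::runif(1L) * atot
    ri <- findInterval(u, cumsum(a), left.open = TRUE) + 1L
    if (ri == 1L) {                         # emergence
      ids <- c(ids, next_id); seeds <- c(seeds, 0L)
      event[s] <- 1L; log_id[s] <- next_id; log_i[s] <- 0L
      next_id <- next_id + 1L
    } else if (ri <= 1L + k) {              # accumulate
      j <- ri - 1L
      seeds[j] <- seeds[j] + 1L; pool <- pool - 1L
      event[s] <- 2L; log_id[s] <- ids[j]; log_i[s] <- seeds[j]
    } else if (ri <= 1L + 2L * k) {         # release
      j <- ri - 1L - k
      seeds[j] <- seeds[j] - 1L; pool <- pool + 1L
      event[s] <- 3L; log_id[s] <- ids[j]; log_i[s] <- seeds[j]
    } else {                                # retract
      j <- ri - 1L - 2L * k
      if (params$seed_return) pool <- pool + seeds[j]
      event[s] <- 4L; log_id[s] <- ids[j]; log_i[s] <- -1L
      ids <- ids[-j]; seeds <- seeds[-j]
    }
    if (params$seed_return &&
        pool + sum(seeds) != total0) {
      stop("internal error: seed conservation violated", call. = FALSE)
    }
    time[s] <- t
    pool_v[s] <- pool
    nfil[s] <- length(seeds)
    nbul[s] <- sum(seeds >= thr)
  }

  structure(list(
    time = time,
    event = factor(ev_names[event], levels = ev_names),
    pool = pool_v, n_filopodia = nfil, n_bulbs = nbul,
    event_log = data.frame(time = time,
                           event = ev_names[event],
                           filo_id = log_id, seeds_after = log_i),
    params = params, seed = as.integer(seed), pool0 = pool0,
    steps = steps),
    class = "mech_history")
}

#' @export
print.mech_history <- function(x, ...) {
  cat(sprintf(
    "Winner-takes-all run: %d steps (%.1f time units), seed %d, %s mode\n",
    x$steps, x$time[x$steps], x$seed, x$params$mode))
  cat(sprintf("  pool: %d -> %d; final filopodia %d, bulbs %d\n",
              x$pool0, x$pool[x$steps], x$n_filopodia[x$steps],
              x$n_bulbs[x$steps]))
  invisible(x)
}

#' @export
plot.mech_history <- function(x, ...) {
  graphics::plot(x$time, x$n_bulbs, type = "s",
                 xlab = "model time", ylab = "bulbous tips", ...)
  invisible(x)
}

#' Bulbous-tip statistics of a winner-takes-all run
#'
#' Discards the burn-in prefix, then (a) tabulates the number of
#' concurrent bulbous tips — filopodia holding at least
#' `bulb_threshold` seeds — over the retained steps (time-weighted by
#' the inter-event waiting times), and (b) reconstructs per-filopodium
#' bulb episodes: each maximal contiguous stretch a filopodium spends
#' at or above the threshold, measured in model time. Episodes still
#' open at the end of the run are flagged censored.
#'
#' @param history a [simulate_mechanistic()] result.
#' @param burn_in_fraction fraction of steps discarded (default 0.5).
#' @return An object of class `"mech_bulb_stats"`: list with
#'   `mean_bulbs` (time-weighted), `count_distribution`
#'   (time-weighted proportions), `lifetimes` data.frame (`filo_id`,
#'   `start`, `end`, `lifetime`, `censored`), `burn_in_fraction`.
#' @export
analyze_bulbs <- function(history, burn_in_fraction = 0.5) {
  stopifnot(inherits(history, "mech_history"))
  steps <- history$steps
  start <- floor(steps * burn_in_fraction) + 1L
  if (!is.finite(start) || start > steps || burn_in_fraction < 0) {
    stop("no steps remain after burn-in", call. = FALSE)
  }
  keep <- seq.int(start, steps)
  thr <- history$params$bulb_threshold
  t0 <- history$time[keep[1L]]
  tt <- history$time[keep]
  dt <- diff(c(t0, tt))
  # state at step s holds until step s+1; weight counts by the following
  # waiting time (last retained state gets zero weight)
  nb <- history$n_bulbs[keep]
  w <- c(dt[-1L], 0)
  wsum <- sum(w)
  cd <- tapply(w, factor(nb, levels = 0:max(nb)), sum)
  cd[is.na(cd)] <- 0
  cd <- cd / wsum

  # episode reconstruction from the event log (post-burn-in only)
  log <- history$event_log[keep, , drop = FALSE]
  t_end <- history$time[steps]
  open_start <- new.env(parent = emptyenv())
  starts <- ends <- numeric(0); fid <- integer(0); cens <- logical(0)
  for (r in seq_len(nrow(log))) {
    id <- as.character(log$filo_id[r]); i_after <- log$seeds_after[r]
    ev <- log$event[r]
    if (ev == "emergence") next
    above <- !is.null(open_start[[id]])
    if (ev == "retract" || i_after < thr) {
      if (above) {
        starts <- c(starts, open_start[[id]]); ends <- c(ends, log$time[r])
        fid <- c(fid, log$filo_id[r]); cens <- c(cens, FALSE)
        rm(list = id, envir = open_start)
      }
    } else if (i_after >= thr && !above) {
      open_start[[id]] <- log$time[r]
    }
  }
  for (id in ls(open_start)) {
    starts <- c(starts, open_start[[id]]); ends <- c(ends, t_end)
    fid <- c(fid, as.integer(id)); cens <- c(cens, TRUE)
  }
  lt <- data.frame(filo_id = fid, start = starts, end = ends,
                   lifetime = ends - starts, censored = cens)

  structure(list(mean_bulbs = sum((as.numeric(names(cd))) * cd),
                 count_distribution = cd,
                 lifetimes = lt,
                 burn_in_fraction = burn_in_fraction,
                 bulb_threshold = thr),
            class = "mech_bulb_stats")
}

#' @export
print.mech_bulb_stats <- function(x, ...) {
  cat(sprintf(
    "Winner-takes-all bulb statistics (threshold %d seeds, burn-in %.0f%%)\n",
    x$bulb_threshold, 100 * x$burn_in_fraction))
  cat(sprintf("  time-weighted mean concurrent bulbs: %.3f\n", x$mean_bulbs))
  cat(sprintf("  bulb episodes: %d (mean lifetime %.2f)\n",
              nrow(x$lifetimes),
              if (nrow(x$lifetimes)) mean(x$lifetimes$lifetime) else NA))
  invisible(x)
}
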
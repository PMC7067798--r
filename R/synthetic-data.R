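# Seeded synthetic-data generators that emulate the observation layer of
# the live-imaging experiments: per-object track tables, per-time-instance
# count snapshots, and bulbous-tip count distributions. Every generator
# returns its inputs in a ground-truth manifest so estimators can be
# validated by parameter recovery.

.manifest <- function(scheme, params, sizes, seed) {
  list(scheme = scheme, params = params, sizes = sizes,
       seed = as.integer(seed),
       package_version = as.character(utils::packageVersion("filosyn")))
}

# rate of the below-cutoff exponential whose truncated mean equals the
# requested class mean; exists iff mean < cutoff/2
.short_class_rate <- function(mean_life, cutoff) {
  if (mean_life >= cutoff / 2) {
    stop("short-class mean lifetime must be < cutoff/2 for a truncated-",
         "exponential class law", call. = FALSE)
  }
  trunc_mean <- function(p) {
    1 / p - cutoff * exp(-p * cutoff) / (1 - exp(-p * cutoff))
  }
  stats::uniroot(function(p) trunc_mean(p) - mean_life,
                 lower = 1e-8, upper = 1e4, tol = 1e-12)$root
}

# one draw per call semantics kept vectorized: n truncated-exponential
# lifetimes below the cutoff (inverse-cdf)
.rtrunc_exp <- function(n, rate, cutoff) {
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate * cutoff))) / rate
}

#' Generate a synthetic filopodium track table
#'
#' Emulates a live-imaging window over one axon terminal. Filopodium
#' classes are defined by their lifetime relative to the 8-min cutoff,
#' so each class is generated as a stationary immigration-death
#' (M/G/infinity) process whose class-conditional lifetime law lives on
#' its side of the cutoff with mean exactly `1/c2`: the short class
#' draws exponential lifetimes truncated below the cutoff (rate chosen
#' so the truncated mean is `1/c2_sF`), the long class draws
#' `cutoff + exponential` lifetimes with overall mean `1/c2_lF`
#' (memoryless beyond the cutoff, i.e. first-order retraction once
#' established). Births arrive as Poisson processes at rate
#' `lambda * c2`, started well before the window so the window is
#' exactly stationary; concurrent counts per time instance are then
#' Poisson(`lambda`) by the M/G/infinity law, and the inverse-mean
#' lifetime estimators are consistent for `c2` by construction.
#' Objects alive at either window boundary are emitted with the
#' censored flag (death time NA) rather than truncated lifetimes.
#'
#' @param lambda_sF,lambda_lF stationary mean concurrent counts.
#' @param c2_sF,c2_lF retraction rates (min^-1); class mean lifetimes
#'   are their inverses, and must respect `1/c2_sF < cutoff/2` and
#'   `1/c2_lF > cutoff`.
#' @param duration imaging-window length (min), default 60.
#' @param snapshot_dt snapshot cadence (min), default 1.
#' @param n_terminals number of independent terminals (windows),
#'   default 8.
#' @param cutoff short/long class boundary (min), default 8.
#' @param seed RNG seed.
#' @return list with `tracks` (data.frame: `terminal`, `object_id`,
#'   `class`, `t_birth_min`, `t_death_min` with NA = censored),
#'   `snapshots` (data.frame: `terminal`, `t_min`, `sF`, `lF`) and
#'   `manifest`.
#' @export
gen_track_table <- function(lambda_sF, lambda_lF, c2_sF, c2_lF,
                            duration = 60, snapshot_dt = 1,
                            n_terminals = 8L, cutoff = 8, seed = 1L) {
  if (duration < snapshot_dt) {
    stop("'duration' must be >= 'snapshot_dt'", call. = FALSE)
  }
  stopifnot(lambda_sF >= 0, lambda_lF >= 0, c2_sF > 0, c2_lF > 0,
            n_terminals >= 1L, cutoff > 0)
  if (1 / c2_lF <= cutoff) {
    stop("long-class mean lifetime 1/c2_lF must exceed the cutoff",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  grid <- seq(0, duration, by = snapshot_dt)
  p_short <- if (lambda_sF > 0) .short_class_rate(1 / c2_sF, cutoff) else NA
  q_long <- 1 / (1 / c2_lF - cutoff)
  # births start early enough that the window is stationary to ~e-12
  warm <- cutoff + 30 / q_long

  sim_class <- function(lambda, c2, class_label, terminal, id0,
                        draw_life) {
    counts <- numeric(length(grid))
    if (lambda == 0) {
      return(list(rows = NULL, counts = counts, next_id = id0))
    }
    n_births <- stats::rpois(1L, lambda * c2 * (warm + duration))
    births <- sort(stats::runif(n_births, -warm, duration))
    deaths <- births + draw_life(n_births)
    keep <- deaths > 0            # objects overlapping the window
    births <- births[keep]; deaths <- deaths[keep]
    n <- length(births)
    if (n == 0L) {
      return(list(rows = NULL, counts = counts, next_id = id0))
    }
    # alive at t iff birth <= t < death
    counts <- findInterval(grid, sort(births)) -
      findInterval(grid, sort(deaths))
    censored <- births < 0 | deaths > duration
    rows <- data.frame(
      terminal = terminal,
      object_id = seq.int(id0, length.out = n),
      class = class_label,
      t_birth_min = pmax(births, 0),
      t_death_min = ifelse(censored, NA_real_, deaths))
    list(rows = rows, counts = counts, next_id = id0 + n)
  }

  all_rows <- list(); snaps <- list()
  for (term in seq_len(n_terminals)) {
    s <- sim_class(lambda_sF, c2_sF, "sF", term, 1L,
                   function(n) .rtrunc_exp(n, p_short, cutoff))
    l <- sim_class(lambda_lF, c2_lF, "lF", term, s$next_id,
                   function(n) cutoff + stats::rexp(n, q_long))
    all_rows <- c(all_rows, list(s$rows), list(l$rows))
    snaps[[term]] <- data.frame(terminal = term, t_min = grid,
                                sF = as.integer(s$counts),
                                lF = as.integer(l$counts))
  }
  all_rows <- all_rows[!vapply(all_rows, is.null, logical(1))]
  tracks <- if (length(all_rows)) do.call(rbind, all_rows)
            else data.frame(terminal = integer(0), object_id = integer(0),
                            class = character(0), t_birth_min = numeric(0),
                            t_death_min = numeric(0))
  rownames(tracks) <- NULL
  list(tracks = tracks,
       snapshots = do.call(rbind, snaps),
       manifest = .manifest(
         "stationary immigration-death tracks (class laws split at cutoff)",
         list(lambda_sF = lambda_sF, lambda_lF = lambda_lF,
              c2_sF = c2_sF, c2_lF = c2_lF, cutoff = cutoff),
         list(duration = duration, snapshot_dt = snapshot_dt,
              n_terminals = n_terminals),
         seed))
}

#' Generate synthetic bulbous-tip count distributions
#'
#' Simulates the exact two-dimensional (sB, synB) continuous-time
#' Markov chain with the same transition semantics as
#' [build_generator()] (Gillespie, constant rates), samples the state
#' on a fixed cadence after discarding a relaxation prefix, and
#' tabulates the empirical marginal count distributions.
#'
#' @param r3 bulb birth-rate prefactor (min^-1; feedback `f1` applied
#'   inside, exactly as in the generator).
#' @param c4,c5,c6 retraction, stabilization, maturation rates
#'   (min^-1).
#' @param B50 feedback half-saturation (> 0).
#' @param total_time simulated time (min); must dwarf the relaxation
#'   time for the empirical law to approximate stationarity.
#' @param sample_dt sampling cadence (min).
#' @param relax_fraction fraction of `total_time` discarded.
#' @param N support cap for the returned distributions.
#' @param f1_mode,generator_mode as in [build_generator()].
#' @param seed RNG seed.
#' @return list with `sB` and `synB` (named empirical probability
#'   vectors on `0..N`), `n_samples`, and `manifest`.
#' @export
gen_bulb_observations <- function(r3, c4, c5, c6, B50,
                                  total_time = 20000, sample_dt = 10,
                                  relax_fraction = 0.1, N = 12L,
                                  f1_mode = "inhibition",
                                  generator_mode = "reaction_consistent",
                                  seed = 1L) {
  stopifnot(r3 >= 0, c4 >= 0, c5 >= 0, c6 >= 0, B50 > 0)
  set.seed(as.integer(seed))
  t <- 0; i <- 0L; j <- 0L
  t_relax <- relax_fraction * total_time
  grid <- seq(t_relax, total_time, by = sample_dt)
  if (length(grid) < 100L) {
    warning("fewer than 100 post-relaxation samples; the empirical ",
            "distributions will be noisy")
  }
  gpos <- 1L
  obs_i <- integer(length(grid)); obs_j <- integer(length(grid))
  while (t < total_time && gpos <= length(grid)) {
    birth <- if (i < N) r3 * eval_f1(j, B50, f1_mode) else 0
    death <- i * c4
    stab <- if (generator_mode == "reaction_consistent") {
      if (j < N) i * c5 else 0
    } else {
      if (j < N) j * c5 else 0
    }
    mat <- j * c6
    a <- c(birth, death, stab, mat)
    atot <- sum(a)
    t_next <- if (atot > 0) t + stats::rexp(1L, atot) else Inf
    while (gpos <= length(grid) && grid[gpos] < t_next) {
      obs_i[gpos] <- i; obs_j[gpos] <- j
      gpos <- gpos + 1L
    }
    if (!is.finite(t_next) || t_next > total_time) break
    t <- t_next
    ri <- findInterval(stats::runif(1L) * atot, cumsum(a),
                       left.open = TRUE) + 1L
    if (ri == 1L) i <- i + 1L
    else if (ri == 2L) i <- i - 1L
    else if (ri == 3L) {
      if (generator_mode == "reaction_consistent") i <- i - 1L
      j <- j + 1L
    } else j <- j - 1L
  }
  used <- seq_len(gpos - 1L)
  tab <- function(x) {
    p <- tabulate(x[used] + 1L, nbins = N + 1L) / length(used)
    stats::setNames(p, 0:N)
  }
  list(sB = tab(obs_i), synB = tab(obs_j), n_samples = length(used),
       manifest = .manifest(
         "2-D bulb CTMC sampled at stationarity",
         list(r3 = r3, c4 = c4, c5 = c5, c6 = c6, B50 = B50,
              f1_mode = f1_mode, generator_mode = generator_mode),
         list(total_time = total_time, sample_dt = sample_dt,
              relax_fraction = relax_fraction, N = N),
         seed))
}

#' Synthetic fixed-timepoint stage summaries
#'
#' Emulates the fixed-preparation counts: runs the developmental
#' simulator once per terminal over the full horizon and summarizes
#' mean and SEM of filopodia (sF + lF), bulbous tips (sB + synB) and
#' synapses at each requested pupal stage.
#'
#' @param params a [dev_params()] (presets carry their drive table).
#' @param stages pupal stages to report (default every 10 from P40 to
#'   P90).
#' @param terminals_per_stage number of simulated terminals (default
#'   40).
#' @param seed RNG seed (one sub-seed per terminal).
#' @param ... passed to [simulate_developmental()].
#' @return list with `summary` (data.frame: stage, mean/SEM per
#'   quantity), `per_terminal` (matrix of final synapse counts) and
#'   `manifest`.
#' @export
gen_fixed_timepoints <- function(params, stages = seq(40, 90, by = 10),
                                 terminals_per_stage = 40L, seed = 1L,
                                 ...) {
  stopifnot(inherits(params, "dev_params"),
            all(stages >= 40), all(stages <= 100))
  t_grid <- stage_to_min(stages)
  t_end <- max(t_grid)
  if (t_end == 0) t_end <- 1   # all-P40 request still needs a horizon
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, terminals_per_stage)
  acc <- array(0, dim = c(terminals_per_stage, length(stages), 3L),
               dimnames = list(NULL, stages,
                               c("filopodia", "bulbs", "synapses")))
  for (k in seq_len(terminals_per_stage)) {
    traj <- simulate_developmental(params, 0, t_end, seed = sub_seeds[k],
                                   ...)
    sn <- snapshot_counts(traj, pmin(t_grid, t_end))
    acc[k, , "filopodia"] <- sn$sF + sn$lF
    acc[k, , "bulbs"] <- sn$sB + sn$synB
    acc[k, , "synapses"] <- sn$S
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summ <- data.frame(
    stage = stages,
    mean_filopodia = apply(acc[, , "filopodia", drop = FALSE], 2, mean),
    sem_filopodia = apply(acc[, , "filopodia", drop = FALSE], 2, sem),
    mean_bulbs = apply(acc[, , "bulbs", drop = FALSE], 2, mean),
    sem_bulbs = apply(acc[, , "bulbs", drop = FALSE], 2, sem),
    mean_synapses = apply(acc[, , "synapses", drop = FALSE], 2, mean),
    sem_synapses = apply(acc[, , "synapses", drop = FALSE], 2, sem),
    row.names = NULL)
  list(summary = summ,
       per_terminal = acc,
       manifest = .manifest(
         "fixed-timepoint stage summaries from developmental simulation",
         unclass(params),
         list(stages = stages, terminals_per_stage = terminals_per_stage),
         seed))
}
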
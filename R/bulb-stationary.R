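# Fast-timescale bulbous-tip inference: the truncated 2-D CTMC over
# (sB, synB) counts, its generator matrix, stationary law, marginals and
# the KL fit of (c5, B50, r3).

.state_index <- function(i, j, N) i + j * (N + 1L) + 1L

#' Build the truncated (sB, synB) generator matrix
#'
#' Assembles the infinitesimal generator of the two-dimensional
#' continuous-time Markov chain over states `[i, j]` with `i` transient
#' bulbs (`sB`) and `j` stabilized synaptogenic bulbs (`synB`),
#' `0 <= i, j <= N`, with reflecting boundary at `N`:
#' bulb birth `[i,j] -> [i+1,j]` at `r3 * f1(j, B50)`, bulb retraction
#' `[i,j] -> [i-1,j]` at `i * c4`, synapse maturation
#' `[i,j] -> [i,j-1]` at `j * c6`, and stabilization either as the
#' reaction `sB -> synB` dictates (`[i,j] -> [i-1,j+1]` at `i * c5`,
#' default) or exactly as typeset in the source model
#' (`[i,j] -> [i,j+1]` at `j * c5`; `generator_mode = "as_printed"`).
#' Diagonal entries are set so every row sums to zero.
#'
#' @param r3 bulb birth-rate prefactor (min^-1), the feedback `f1`
#'   excluded.
#' @param c4,c5,c6 retraction, stabilization and maturation constants
#'   (min^-1).
#' @param B50 feedback half-saturation count (> 0).
#' @param N truncation: maximum count per species.
#' @param f1_mode feedback form, see [eval_f1()].
#' @param generator_mode `"reaction_consistent"` (default) or
#'   `"as_printed"`.
#' @return An object of class `"bulb_generator"`: list with the dense
#'   `matrix` (`(N+1)^2` square, states ordered `i` fastest), `N`, the
#'   rates and modes, and a `states` data.frame mapping rows to
#'   `(i, j)`.
#' @export
#' @examples
#' g <- build_generator(r3 = 0.02, c4 = 1/120, c5 = 0.01, c6 = 1/132,
#'                      B50 = 2, N = 8)
#' max(abs(rowSums(g$matrix)))   # 0 to machine precision
build_generator <- function(r3, c4, c5, c6, B50, N = 15L,
                            f1_mode = c("inhibition", "as_printed"),
                            generator_mode = c("reaction_consistent",
                                               "as_printed")) {
  f1_mode <- match.arg(f1_mode)
  generator_mode <- match.arg(generator_mode)
  rates <- c(r3 = r3, c4 = c4, c5 = c5, c6 = c6)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(B50) || B50 <= 0) {
    stop("'B50' must be positive", call. = FALSE)
  }
  N <- as.integer(N)
  if (N < 1L) stop("truncation 'N' must be >= 1", call. = FALSE)

  M <- (N + 1L)^2
  G <- matrix(0, M, M)
  for (j in 0:N) {
    f1j <- eval_f1(j, B50, f1_mode)
    for (i in 0:N) {
      from <- .state_index(i, j, N)
      if (i > 0L) G[from, .state_index(i - 1L, j, N)] <- i * c4
      if (j > 0L) G[from, .state_index(i, j - 1L, N)] <- j * c6
      if (i < N)  G[from, .state_index(i + 1L, j, N)] <- r3 * f1j
      if (generator_mode == "reaction_consistent") {
        if (i > 0L && j < N) {
          G[from, .state_index(i - 1L, j + 1L, N)] <-
            G[from, .state_index(i - 1L, j + 1L, N)] + i * c5
        }
      } else {
        if (j < N) {
          G[from, .state_index(i, j + 1L, N)] <-
            G[from, .state_index(i, j + 1L, N)] + j * c5
        }
      }
    }
  }
  diag(G) <- -rowSums(G)
  states <- expand.grid(i = 0:N, j = 0:N, KEEP.OUT.ATTRS = FALSE)
  structure(list(matrix = G, N = N, r3 = r3, c4 = c4, c5 = c5, c6 = c6,
                 B50 = B50, f1_mode = f1_mode,
                 generator_mode = generator_mode, states = states),
            class = "bulb_generator")
}

#' @export
print.bulb_generator <- function(x, ...) {
  cat(sprintf(
    "Bulbous-tip generator: N = %d (%d states), mode = %s, f1 = %s\n",
    x$N, nrow(x$matrix), x$generator_mode, x$f1_mode))
  cat(sprintf("  r3 = %.4g, c4 = %.4g, c5 = %.4g, c6 = %.4g, B50 = %.4g\n",
              x$r3, x$c4, x$c5, x$c6, x$B50))
  invisible(x)
}

# communicating classes of the chain on the positive-rate support,
# via boolean transitive closure (repeated squaring)
.communicating_classes <- function(G) {
  A <- (G > 0); diag(A) <- TRUE
  R <- A
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  mutual <- R & t(R)
  comp <- integer(nrow(G)); cur <- 0L
  for (s in seq_len(nrow(G))) {
    if (comp[s] == 0L) { cur <- cur + 1L; comp[mutual[s, ]] <- cur }
  }
  comp
}

#' Stationary distribution of a bulbous-tip generator
#'
#' Solves the eigenvalue problem `t(G) v = lambda v` and returns the
#' eigenvector for the eigenvalue of smallest magnitude (analytically
#' zero for a proper generator), normalized to a probability vector.
#' Negative round-off entries are clamped to zero and the vector
#' renormalized; the residual `max |t(G) v|` is reported.
#'
#' @param gen a [build_generator()] object.
#' @param tol tolerance used to detect a reducible chain (more than one
#'   zero eigenvalue).
#' @return An object of class `"stationary_distribution"`: list with
#'   `pi` (probability vector over the flattened states), `eigenvalue`,
#'   `residual`, and the generator's `N` and `states`.
#' @export
stationary_distribution <- function(gen, tol = 1e-8) {
  stopifnot(inherits(gen, "bulb_generator"))
  G <- gen$matrix
  scale <- max(abs(G), 1)
  e <- eigen(t(G))
  mag <- Mod(e$values)
  k <- which.min(mag)
  if (sum(mag < tol * scale) > 1L) {
    comp <- .communicating_classes(G)
    stop(sprintf(
      paste("generator is reducible: %d disconnected communicating",
            "classes (sizes %s); the stationary distribution is not",
            "unique"),
      max(comp), paste(table(comp), collapse = ", ")), call. = FALSE)
  }
  v <- Re(e$vectors[, k])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8 * max(abs(v)))) {
    warning("stationary eigenvector has non-trivial negative entries; ",
            "clamping to zero")
  }
  v[v < 0] <- 0
  v <- v / sum(v)
  structure(list(pi = v,
                 eigenvalue = Re(e$values[k]),
                 residual = max(abs(crossprod(G, v))),
                 N = gen$N, states = gen$states),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  m <- marginal_densities(x)
  cat(sprintf(
    "Stationary distribution on [0, %d]^2 (eigenvalue %.3g, residual %.3g)\n",
    x$N, x$eigenvalue, x$residual))
  cat(sprintf("  E[sB] = %.3f, E[synB] = %.3f, E[total] = %.3f\n",
              m$mean_sB, m$mean_synB, m$mean_sB + m$mean_synB))
  invisible(x)
}

#' Marginal count densities of a stationary distribution
#'
#' Sums the stationary law over the other species to obtain the
#' marginal distributions of the transient (`sB`) and stabilized
#' (`synB`) bulb counts on support `0..N`.
#'
#' @param v a [stationary_distribution()] object.
#' @return An object of class `"bulb_distribution"`: list with `sB` and
#'   `synB` probability vectors (names `0..N`), their means, and `N`.
#' @export
marginal_densities <- function(v) {
  stopifnot(inherits(v, "stationary_distribution"))
  N <- v$N
  P <- matrix(v$pi, N + 1L, N + 1L)      # rows i (sB), cols j (synB)
  p_sB <- rowSums(P); p_synB <- colSums(P)
  names(p_sB) <- names(p_synB) <- 0:N
  structure(list(sB = p_sB, synB = p_synB,
                 mean_sB = sum((0:N) * p_sB),
                 mean_synB = sum((0:N) * p_synB),
                 N = N, provenance = "model"),
            class = "bulb_distribution")
}

#' Kullback-Leibler divergence between count distributions
#'
#' `KL(p_obs || p_model) = sum p_obs log(p_obs / p_model)` in nats,
#' after adding `pseudocount` to every bin of both distributions and
#' renormalizing. With a zero pseudocount, a model bin of probability
#' zero where the observation has mass yields `+Inf` with a warning.
#'
#' @param p_obs,p_model probability vectors on the same support.
#' @param pseudocount non-negative regularizer added to each bin
#'   (default 1e-6).
#' @return non-negative scalar (nats); 0 iff the inputs are identical.
#' @export
#' @examples
#' kl_divergence(c(.5, .5), c(.9, .1), pseudocount = 0)  # 0.5108...
kl_divergence <- function(p_obs, p_model, pseudocount = 1e-6) {
  if (length(p_obs) != length(p_model)) {
    stop("distributions must share the same support length", call. = FALSE)
  }
  if (pseudocount < 0) stop("'pseudocount' must be >= 0", call. = FALSE)
  p <- p_obs + pseudocount; q <- p_model + pseudocount
  p <- p / sum(p); q <- q / sum(q)
  if (any(q == 0 & p > 0)) {
    warning("model assigns zero probability where observations have mass; ",
            "KL divergence is infinite")
    return(Inf)
  }
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Choose a truncation with negligible tail mass
#'
#' Starting from `N`, enlarges the truncation until the stationary mass
#' within one count of the reflecting boundary (`max(i, j) >= N - 1`)
#' is below `tail_tol`, so results are insensitive to the boundary.
#'
#' @inheritParams build_generator
#' @param N starting truncation (default 15).
#' @param tail_tol boundary-mass threshold (default 1e-6).
#' @param N_max hard cap.
#' @return chosen integer truncation.
#' @export
choose_truncation <- function(r3, c4, c5, c6, B50, N = 15L,
                              f1_mode = "inhibition",
                              generator_mode = "reaction_consistent",
                              tail_tol = 1e-6, N_max = 60L) {
  repeat {
    gen <- build_generator(r3, c4, c5, c6, B50, N, f1_mode, generator_mode)
    v <- stationary_distribution(gen)
    tail <- with(v$states, sum(v$pi[pmax(i, j) >= N - 1L]))
    if (tail < tail_tol || N >= N_max) return(as.integer(N))
    N <- min(N + 5L, N_max)
  }
}

#' Fit (c5, B50, r3) to observed bulbous-tip count distributions
#'
#' Estimates the stabilization constant `c5`, the feedback
#' half-saturation `B50` and the bulb birth-rate prefactor `r3` by
#' minimizing the sum of the Kullback-Leibler divergences between the
#' observed and model-predicted marginal count distributions of
#' transient (`sB`) and stabilized (`synB`) bulbous tips, with `c4` and
#' `c6` fixed externally. Positivity is enforced by optimizing on the
#' log scale; the optimizer is a derivative-free Nelder-Mead refinement
#' of the best points of a data-informed 5 x 5 x 5 log-spaced grid, so
#' the fit is deterministic.
#'
#' @param obs_sB,obs_synB observed probability vectors on support
#'   `0..N` (length `N + 1`); counts are normalized if needed.
#' @param c4,c6 fixed retraction and maturation constants (min^-1).
#' @param N truncation; defaults to `length(obs_sB) - 1`.
#' @param f1_mode,generator_mode passed to [build_generator()].
#' @param pseudocount KL regularizer per bin.
#' @param kl_weights length-2 weights for the (sB, synB) KL terms;
#'   equal by default.
#' @return An object of class `"bulb_fit"`: list with `coefficients`
#'   (`c5`, `B50`, `r3`), `objective`, fitted `model` marginals,
#'   `observed` marginals, the grid of `starts`, convergence info and
#'   settings. `coef`, `print` and `summary` methods apply.
#' @export
fit_bulbs <- function(obs_sB, obs_synB, c4 = 1 / 120, c6 = 5 / 660,
                      N = length(obs_sB) - 1L,
                      f1_mode = "inhibition",
                      generator_mode = "reaction_consistent",
                      pseudocount = 1e-6,
                      kl_weights = c(1, 1)) {
  if (length(obs_sB) != N + 1L || length(obs_synB) != N + 1L) {
    stop("observed distributions must have length N + 1", call. = FALSE)
  }
  if (any(obs_sB < 0) || any(obs_synB < 0)) {
    stop("observed distributions must be non-negative", call. = FALSE)
  }
  obs_sB <- obs_sB / sum(obs_sB)
  obs_synB <- obs_synB / sum(obs_synB)
  supp <- 0:N
  m_sB <- sum(supp * obs_sB); m_synB <- sum(supp * obs_synB)

  unidentifiable <- (m_sB == 0 && m_synB == 0)
  if (unidentifiable) {
    warning("all observed mass at zero for both species; ",
            "(c5, B50, r3) are unidentifiable — returning a boundary fit")
  }

  objective <- function(lpar) {
    c5 <- exp(lpar[1L]); B50 <- exp(lpar[2L]); r3 <- exp(lpar[3L])
    gen <- build_generator(r3, c4, c5, c6, B50, N, f1_mode, generator_mode)
    v <- stationary_distribution(gen)
    m <- marginal_densities(v)
    kl_weights[1L] * kl_divergence(obs_sB, m$sB, pseudocount) +
      kl_weights[2L] * kl_divergence(obs_synB, m$synB, pseudocount)
  }

  # data-informed grid centres: moment-match the quasi birth-death fluxes
  c5_0 <- max(c6 * m_synB / max(m_sB, 0.05), 1e-4)
  r3_0 <- max(m_sB, 0.05) * (c4 + c5_0)
  grid <- expand.grid(
    lc5 = log(c5_0) + log(10) * seq(-1, 1, length.out = 5),
    lB50 = log(c(0.5, 1, 2, 4, 8)),
    lr3 = log(r3_0) + log(10) * seq(-1, 1, length.out = 5))
  grid$value <- apply(grid[, 1:3], 1L, objective)
  ord <- order(grid$value)

  best <- NULL
  for (k in ord[1:3]) {
    fit <- stats::optim(as.numeric(grid[k, 1:3]), objective,
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-9))
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  co <- stats::setNames(exp(best$par), c("c5", "B50", "r3"))
  gen <- build_generator(co["r3"], c4, co["c5"], c6, co["B50"], N,
                         f1_mode, generator_mode)
  m <- marginal_densities(stationary_distribution(gen))

  structure(list(
    coefficients = co,
    objective = best$value,
    convergence = best$convergence,
    model = m,
    observed = list(sB = stats::setNames(obs_sB, supp),
                    synB = stats::setNames(obs_synB, supp)),
    starts = grid,
    fixed = c(c4 = c4, c6 = c6),
    N = N, f1_mode = f1_mode, generator_mode = generator_mode,
    pseudocount = pseudocount, kl_weights = kl_weights,
    unidentifiable = unidentifiable),
    class = "bulb_fit")
}

#' @export
coef.bulb_fit <- function(object, ...) object$coefficients

#' @export
print.bulb_fit <- function(x, ...) {
  cat("Bulbous-tip stationary KL fit\n")
  cat(sprintf("  c5 = %.4g, B50 = %.4g, r3 = %.4g   (KL objective %.4g)\n",
              x$coefficients["c5"], x$coefficients["B50"],
              x$coefficients["r3"], x$objective))
  cat(sprintf("  fixed: c4 = %.4g, c6 = %.4g; N = %d; %s / %s\n",
              x$fixed["c4"], x$fixed["c6"], x$N, x$generator_mode,
              x$f1_mode))
  if (x$unidentifiable) cat("  WARNING: unidentifiable boundary fit\n")
  invisible(x)
}

#' @export
summary.bulb_fit <- function(object, ...) {
  obs_mean <- c(sB = sum(as.numeric(names(object$observed$sB)) *
                           object$observed$sB),
                synB = sum(as.numeric(names(object$observed$synB)) *
                             object$observed$synB))
  structure(list(fit = object,
                 obs_mean = obs_mean,
                 model_mean = c(sB = object$model$mean_sB,
                                synB = object$model$mean_synB)),
            class = "summary.bulb_fit")
}

#' @export
print.summary.bulb_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean sB:   observed %.3f, fitted %.3f\n",
              x$obs_mean["sB"], x$model_mean["sB"]))
  cat(sprintf("  mean synB: observed %.3f, fitted %.3f\n",
              x$obs_mean["synB"], x$model_mean["synB"]))
  invisible(x)
}

#' @export
plot.bulb_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (sp in c("sB", "synB")) {
    obs <- x$observed[[sp]]; mod <- x$model[[sp]]
    graphics::barplot(rbind(obs, mod), beside = TRUE,
                      names.arg = names(obs), col = c("grey40", "grey80"),
                      main = sp, xlab = "count", ylab = "probability", ...)
    graphics::legend("topright", c("observed", "fitted"),
                     fill = c("grey40", "grey80"), bty = "n")
  }
  invisible(x)
}

#' Stationary bulbous-tip summary for a genotype at a stage
#'
#' Convenience wrapper: derives the bulb birth-rate prefactor at the
#' requested stage, `r3 = c3 * (sF + lF) * f_FB(t)`, from a genotype's
#' developmental parameters and mean filopodium counts, builds the
#' generator at a truncation chosen by [choose_truncation()], and
#' returns the stationary marginals and means.
#'
#' @param params a [dev_params()]; if it carries a `lambda_P60`
#'   attribute (as the presets do) and `lambda_tot` is missing, the sum
#'   of those mean counts is used.
#' @param stage pupal stage (default 60).
#' @param lambda_tot mean total filopodium count at the stage.
#' @return a [marginal_densities()] object with the generator attached
#'   as attribute `"generator"`.
#' @export
stationary_bulb_summary <- function(params, stage = 60, lambda_tot = NULL) {
  stopifnot(inherits(params, "dev_params"))
  if (is.null(lambda_tot)) {
    lam <- attr(params, "lambda_P60")
    if (is.null(lam)) {
      stop("supply 'lambda_tot' (mean filopodium count at the stage)",
           call. = FALSE)
    }
    lambda_tot <- sum(lam)
  }
  t_ref <- stage_to_min(stage)
  r3 <- params$c3 * lambda_tot * eval_f_FB(t_ref, params$t_half)
  N <- choose_truncation(r3, params$c4, params$c5, params$c6, params$B50,
                         f1_mode = params$f1_mode)
  gen <- build_generator(r3, params$c4, params$c5, params$c6, params$B50,
                         N, params$f1_mode)
  m <- marginal_densities(stationary_distribution(gen))
  attr(m, "generator") <- gen
  m
}
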
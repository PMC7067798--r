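# Shared fixtures: small parameter sets and a forged stationary object
# for marginal tests.

const_drive_params <- function(...) {
  # flat drive polynomial (f_F == 1) so only explicit rates act
  dev_params(poly_coeffs = c(1, 0, 0, 0, 0, 0), ...)
}

# a stationary_distribution object with prescribed probabilities, for
# testing marginalization independently of the eigen solver
forge_stationary <- function(P) {
  N <- nrow(P) - 1L
  structure(list(pi = as.numeric(P), eigenvalue = 0, residual = 0,
                 N = N,
                 states = expand.grid(i = 0:N, j = 0:N,
                                      KEEP.OUT.ATTRS = FALSE)),
            class = "stationary_distribution")
}
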
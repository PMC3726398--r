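#' Hyperparameters of the edge-selection model
#'
#' Collects the prior hyperparameters used by the marginal configuration
#' score. The defaults encode the standard sparse-network assumptions:
#' a Beta(1, 2) prior on the edge-presence probability (mass tilted toward
#' sparse networks), a flat inverse-gamma IG(1, 1) prior on the residual
#' noise variance, a unit-information g-prior scale (`c` equal to the number
#' of admissible perturbations of each subnetwork), and a ridge parameter
#' `lambda = 0.1` that keeps the slab covariance positive definite even when
#' fewer perturbations than candidate regulators are available.
#'
#' @param a Beta shape for edge presence. Default 1.
#' @param b Beta shape for edge absence. Default 2; `a < b` favours sparsity.
#' @param alpha Inverse-gamma shape of the noise variance prior. Default 1.
#' @param beta Inverse-gamma scale of the noise variance prior. Default 1.
#' @param c g-prior scale. `NA` (default) resolves to `n_pi`, the number of
#'   admissible perturbations of the subproblem being scored.
#' @param lambda Ridge parameter stabilizing the slab precision; must lie in
#'   (0, 1). Default 0.1.
#' @return An object of class `"bvsa_hyper"` (a named list).
#' @examples
#' bvsa_hyper()
#' bvsa_hyper(c = 10, lambda = 0.5)
#' @export
bvsa_hyper <- function(a = 1, b = 2, alpha = 1, beta = 1, c = NA,
                       lambda = 0.1) {
  stopifnot(a > 0, b > 0, alpha > 0, beta > 0,
            is.na(c) || c > 0,
            lambda > 0, lambda < 1)
  structure(list(a = a, b = b, alpha = alpha, beta = beta, c = c,
                 lambda = lambda),
            class = "bvsa_hyper")
}

#' @export
print.bvsa_hyper <- function(x, ...) {
  cat("Edge-selection hyperparameters:\n")
  cat(sprintf("  Beta edge prior:        a = %g, b = %g\n", x$a, x$b))
  cat(sprintf("  IG noise prior:         alpha = %g, beta = %g\n",
              x$alpha, x$beta))
  cat(sprintf("  g-prior scale c:        %s\n",
              if (is.na(x$c)) "n_pi (per subproblem)" else format(x$c)))
  cat(sprintf("  ridge lambda:           %g\n", x$lambda))
  invisible(x)
}

# resolve the g-prior scale for a subproblem with n_pi admissible columns
resolve_c <- function(hyper, n_pi) {
  if (is.na(hyper$c)) n_pi else hyper$c
}

#' Gibbs chain settings
#'
#' Settings for the parallel Gibbs samplers used to approximate the
#' posterior over regulator configurations. Five parallel chains with a 20%
#' burn-in are the defaults; `n_sweeps` should be raised for noisy data
#' (500) and for real datasets (2000), while 200 suffices for clean
#' simulated responses.
#'
#' @param n_chains Number of independent chains. Default 5.
#' @param n_sweeps Number of full Gibbs sweeps (one recorded sample per
#'   sweep). Default 500.
#' @param burn_in Fraction of initial samples discarded. Default 0.2.
#' @return An object of class `"bvsa_chains"`.
#' @examples
#' bvsa_chains(n_sweeps = 200)
#' @export
bvsa_chains <- function(n_chains = 5, n_sweeps = 500, burn_in = 0.2) {
  stopifnot(n_chains >= 1, n_sweeps >= 1, burn_in >= 0, burn_in < 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_sweeps = as.integer(n_sweeps),
                 burn_in = burn_in,
                 n_burn = as.integer(floor(burn_in * n_sweeps))),
            class = "bvsa_chains")
}
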
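#' Infer network topology by Bayesian variable selection
#'
#' Fits the Bayesian variable selection model to a global response matrix:
#' the network is divided into one subnetwork per node (the node and its
#' candidate regulators), each subnetwork's posterior over regulator
#' configurations is approximated independently — by parallel Gibbs
#' samplers or, for small networks, exhaustive enumeration — and the
#' per-edge marginal posteriors are assembled into an n x n probability
#' matrix `P`, where `P[i, j]` is the posterior probability that node `j`
#' directly influences node `i`. Self-edges are not modeled (diagonal
#' `NA`).
#'
#' @param R Node x experiment global response matrix (see
#'   [response_matrix()]).
#' @param design A [bvsa_design()] covering the columns of `R`.
#' @param hyper A [bvsa_hyper()].
#' @param settings A [bvsa_chains()] (ignored when `engine =
#'   "exhaustive"`).
#' @param engine `"gibbs"` (default) or `"exhaustive"`.
#' @param standardize Row-standardize `R` first (divide each row by its
#'   population standard deviation). Default `TRUE`, matching the standard
#'   reconstruction protocol; set `FALSE` if `R` is already standardized.
#' @param seed Optional integer seed for the Gibbs chains.
#' @return An object of class `"bvsa"`: list with `P` (posterior edge
#'   probability matrix), `traces` (per node, engine `"gibbs"`),
#'   `exact` (per node, engine `"exhaustive"`), `nodes`, `hyper`,
#'   `settings`, `engine`, `call`.
#' @examples
#' net <- mapk_network()
#' sim <- simulate_knockdowns(net, seed = 1)
#' R <- response_matrix(sim$states, "baseline", sim$design)
#' fit <- bvsa(R, sim$design, settings = bvsa_chains(n_sweeps = 100),
#'             seed = 1)
#' round(coef(fit), 2)
#' @export
bvsa <- function(R, design, hyper = bvsa_hyper(),
                 settings = bvsa_chains(),
                 engine = c("gibbs", "exhaustive"),
                 standardize = TRUE, seed = NULL) {
  engine <- match.arg(engine)
  R <- as.matrix(R)
  if (standardize) R <- standardize_rows(R)
  nodes <- rownames(R)
  n <- length(nodes)
  if (n < 2) stop("need at least two nodes")
  if (!is.null(seed)) set.seed(seed)

  P <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  traces <- exact <- setNames(vector("list", n), nodes)
  for (node in nodes) {
    prob <- subproblem(R, design, node)
    if (engine == "exhaustive") {
      ex <- exhaustive_posterior(prob, hyper)
      exact[[node]] <- ex
      P[node, prob$candidates] <- ex$marginals
    } else {
      trs <- lapply(seq_len(settings$n_chains), function(k)
        run_chain(prob, hyper, settings))
      traces[[node]] <- trs
      P[node, prob$candidates] <-
        posterior_edge_probabilities(trs, settings)
    }
  }
  structure(list(P = P, traces = traces, exact = exact, nodes = nodes,
                 hyper = hyper, settings = settings, engine = engine,
                 standardized = standardize, call = match.call()),
            class = "bvsa")
}

#' @export
print.bvsa <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Bayesian variable selection network fit (%d nodes, engine: %s)\n\n",
    length(x$nodes), x$engine))
  cat("Posterior edge probabilities P[i, j] = P(j -> i):\n")
  print(round(x$P, digits))
  invisible(x)
}

#' Extract posterior edge probabilities
#'
#' @param object A [bvsa()] fit.
#' @param ... Unused.
#' @return The n x n posterior edge probability matrix (`NA` diagonal).
#' @export
coef.bvsa <- function(object, ...) object$P

#' @export
summary.bvsa <- function(object, scheme = c("mean", "mpm", "fixed"),
                         value = NULL, ...) {
  scheme <- match.arg(scheme)
  called <- threshold_edges(object$P, scheme, value)
  structure(list(fit = object, network = called), class = "summary.bvsa")
}

#' @export
print.summary.bvsa <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$network)
  invisible(x)
}

#' Plot Gibbs chain diagnostics
#'
#' Plots the per-sweep log marginal score of each parallel chain for one
#' node's subnetwork: overlapping traces indicate that the chains have
#' converged on the same configuration distribution.
#'
#' @param x A [bvsa()] fit with `engine = "gibbs"`.
#' @param node Node whose chains to plot (default: first).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bvsa <- function(x, node = x$nodes[1], ...) {
  trs <- x$traces[[node]]
  if (is.null(trs))
    stop("no chain traces stored (engine was not 'gibbs')")
  ls <- vapply(trs, function(tr) tr$log_scores,
               numeric(length(trs[[1]]$log_scores)))
  graphics::matplot(ls, type = "l", lty = 1,
                    xlab = "sweep", ylab = "log posterior score",
                    main = sprintf("Gibbs chains, node '%s'", node), ...)
  invisible(x)
}

#' Call edges by thresholding posterior probabilities
#'
#' Converts a posterior edge probability matrix into a binary adjacency by
#' thresholding: an edge `j -> i` is called when `P[i, j] >= p_th`.
#' Schemes: `"mean"` sets the threshold to the average off-diagonal
#' posterior probability (when probabilities are spread uniformly this is
#' close to 0.5 and coincides with the Median Probability Model, but under
#' collinear data it adapts downward); `"mpm"` is the Median Probability
#' Model, `p_th = 0.5`; `"fixed"` uses the supplied `value`.
#'
#' @param P Posterior edge probability matrix (diagonal ignored).
#' @param scheme `"mean"`, `"mpm"`, or `"fixed"`.
#' @param value Threshold for `scheme = "fixed"`.
#' @return Object of class `"bvsa_network"`: list with `A` (binary
#'   adjacency, `A[i, j] = 1` meaning `j -> i`, zero diagonal),
#'   `threshold`, `scheme`.
#' @examples
#' P <- matrix(c(NA, 0.8, 0.2, NA), 2, 2,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' threshold_edges(P, "mean")
#' @export
threshold_edges <- function(P, scheme = c("mean", "mpm", "fixed"),
                            value = NULL) {
  scheme <- match.arg(scheme)
  P <- as.matrix(P)
  n <- nrow(P)
  if (n < 2) stop("need at least two nodes")
  off <- !diag(n)
  p_th <- switch(scheme,
                 mean = mean(P[off], na.rm = TRUE),
                 mpm = 0.5,
                 fixed = {
                   if (is.null(value) || value < 0 || value > 1)
                     stop("scheme 'fixed' needs a threshold in [0, 1]")
                   value
                 })
  A <- matrix(0L, n, n, dimnames = dimnames(P))
  A[off] <- as.integer(!is.na(P[off]) & P[off] >= p_th)
  structure(list(A = A, threshold = p_th, scheme = scheme),
            class = "bvsa_network")
}

#' @export
print.bvsa_network <- function(x, ...) {
  cat(sprintf("Called network (%s threshold p_th = %.3f): %d edge(s)\n",
              x$scheme, x$threshold, sum(x$A)))
  edges <- which(x$A == 1, arr.ind = TRUE)
  if (nrow(edges)) {
    nm <- rownames(x$A)
    for (e in seq_len(nrow(edges)))
      cat(sprintf("  %s -> %s\n", nm[edges[e, 2]], nm[edges[e, 1]]))
  }
  invisible(x)
}
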
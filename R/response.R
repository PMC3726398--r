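#' Global response coefficient of a single node
#'
#' Fractional steady-state change of a node after a perturbation,
#' `2 (xk - x0) / (xk + x0)`, where `x0` and `xk` are the steady-state
#' activities before and after the perturbation. Values lie in (-2, 2]; a
#' full knockout of the measured node itself gives the limit -2.
#'
#' @param x0 Baseline steady-state value (strictly positive).
#' @param xk Perturbed steady-state value (non-negative).
#' @return The global response coefficient(s); vectorized over inputs.
#' @examples
#' global_response(1, 3)   # 1
#' global_response(1, 1)   # 0
#' @export
global_response <- function(x0, xk) {
  if (any(!is.finite(x0)) || any(!is.finite(xk)))
    stop("non-finite steady-state values")
  if (any(x0 <= 0)) stop("baseline steady-state values must be positive")
  if (any(xk < 0)) stop("perturbed steady-state values must be non-negative")
  2 * (xk - x0) / (xk + x0)
}

#' Perturbation design table
#'
#' Validates a design table mapping each perturbation experiment to the
#' single node it directly targets, with optional knockdown efficiency and
#' replicate annotations. Each experiment must target exactly one node;
#' several experiments may target the same node (e.g. repeated knockdowns
#' at different efficiencies).
#'
#' @param experiment Character vector of experiment identifiers (unique).
#' @param target Character vector: the node each experiment perturbs.
#' @param efficiency Optional numeric in (0, 1]: knockdown efficiency.
#' @param replicate Optional integer replicate index.
#' @return A `data.frame` of class `"bvsa_design"` with columns
#'   `experiment`, `target`, `efficiency`, `replicate`.
#' @export
bvsa_design <- function(experiment, target, efficiency = NA_real_,
                        replicate = NA_integer_) {
  experiment <- as.character(experiment)
  target <- as.character(target)
  if (anyDuplicated(experiment))
    stop("duplicated experiment identifiers in design")
  if (length(target) != length(experiment))
    stop("each experiment must map to exactly one target node")
  eff <- rep_len(as.numeric(efficiency), length(experiment))
  if (any(!is.na(eff) & (eff <= 0 | eff > 1)))
    stop("knockdown efficiency must lie in (0, 1]")
  d <- data.frame(experiment = experiment, target = target,
                  efficiency = eff,
                  replicate = rep_len(as.integer(replicate),
                                      length(experiment)),
                  stringsAsFactors = FALSE)
  class(d) <- c("bvsa_design", "data.frame")
  d
}

#' Build the global response matrix from steady-state measurements
#'
#' Applies the global response formula column-by-column against an explicit
#' baseline (unperturbed) column. Rows are nodes, columns are perturbation
#' experiments; the baseline column is consumed, not returned.
#'
#' @param states Numeric node x experiment matrix of steady-state values
#'   with row and column names. Must include the baseline column.
#' @param baseline Name of the unperturbed baseline column.
#' @param design A [bvsa_design()] covering every non-baseline column.
#' @return A node x perturbation matrix of global response coefficients
#'   with attribute `standardized = FALSE`.
#' @examples
#' states <- cbind(b = c(n1 = 1, n2 = 1), e1 = c(3, 1))
#' design <- bvsa_design("e1", "n1")
#' response_matrix(states, "b", design)
#' @export
response_matrix <- function(states, baseline, design) {
  states <- as.matrix(states)
  if (is.null(rownames(states)) || is.null(colnames(states)))
    stop("steady-state table needs node row names and experiment column names")
  if (!baseline %in% colnames(states))
    stop("baseline column '", baseline, "' not found in steady-state table")
  pert <- setdiff(colnames(states), baseline)
  missing <- setdiff(pert, design$experiment)
  if (length(missing))
    stop("experiments missing from design: ", paste(missing, collapse = ", "))
  bad <- design$target[!design$target %in% rownames(states)]
  if (length(bad))
    stop("design targets not among nodes: ", paste(bad, collapse = ", "))
  x0 <- states[, baseline]
  zero <- rownames(states)[x0 <= 0]
  if (length(zero))
    stop("non-positive baseline value for node(s): ",
         paste(zero, collapse = ", "))
  R <- vapply(pert, function(k) global_response(x0, states[, k]),
              numeric(nrow(states)))
  dimnames(R) <- list(rownames(states), pert)
  attr(R, "standardized") <- FALSE
  R
}

#' Row-standardize a response matrix
#'
#' Divides each row of the global response matrix by its standard deviation
#' so that every node contributes equal variability to the inference. The
#' population convention (divide by `n`) is used; the result is idempotent
#' under repeated application.
#'
#' @param R Node x experiment response matrix.
#' @return The standardized matrix, attribute `standardized = TRUE`.
#' @export
standardize_rows <- function(R) {
  R <- as.matrix(R)
  sds <- apply(R, 1, pop_sd)
  flat <- which(sds == 0 | !is.finite(sds))
  if (length(flat))
    stop("constant (uninformative) response row for node(s): ",
         paste(rownames(R)[flat], collapse = ", "))
  out <- R / sds
  attr(out, "standardized") <- TRUE
  out
}

# population standard deviation (divide by n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-node subnetwork inference problem
#'
#' Restricts the response matrix to the perturbations admissible for one
#' node: the columns whose design target is not the node itself. Returns
#' the node's own response row together with the candidate-regulator block
#' stacking all other nodes' rows over the same columns.
#'
#' @param R Node x experiment response matrix.
#' @param design A [bvsa_design()] covering the columns of `R`.
#' @param node Node (row) label to build the problem for.
#' @return An object of class `"bvsa_subproblem"`: a list with elements
#'   `node`, `candidates` (ordered labels of the other nodes), `R_i`
#'   (length-`n_pi` response row), `R_pr` ((n-1) x `n_pi` candidate block),
#'   `n_pi`, and `experiments` (retained column labels).
#' @export
subproblem <- function(R, design, node) {
  R <- as.matrix(R)
  if (!node %in% rownames(R)) stop("unknown node '", node, "'")
  tgt <- design$target[match(colnames(R), design$experiment)]
  if (anyNA(tgt))
    stop("design does not cover all response columns")
  keep <- which(tgt != node)
  if (!length(keep))
    stop("node '", node, "' is unidentifiable: every perturbation targets it")
  candidates <- setdiff(rownames(R), node)
  structure(list(node = node,
                 candidates = candidates,
                 R_i = R[node, keep],
                 R_pr = R[candidates, keep, drop = FALSE],
                 n_pi = length(keep),
                 experiments = colnames(R)[keep]),
            class = "bvsa_subproblem")
}

#' @export
print.bvsa_subproblem <- function(x, ...) {
  cat(sprintf("Subnetwork problem for node '%s': %d candidate regulators, %d admissible perturbations\n",
              x$node, length(x$candidates), x$n_pi))
  invisible(x)
}
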
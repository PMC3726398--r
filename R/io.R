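#' Read and write node x experiment matrices as TSV
#'
#' Matrices are exchanged as tab-separated text: header row of experiment
#' (or node) identifiers, first column of node identifiers, decimal-point
#' floats, `NA` for unmodeled entries (e.g. the diagonal of a posterior
#' edge probability matrix).
#'
#' @param path File path.
#' @return `read_matrix_tsv`: a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("matrix TSV needs an id column plus data columns")
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in matrix TSV: ", path)
  rownames(m) <- as.character(d[[1]])
  m
}

#' @param m Matrix to write.
#' @param id_name Header of the identifier column. Default `"node"`.
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(m, path, id_name = "node") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_name
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a perturbation design table from TSV
#'
#' Expects columns `experiment_id`, `target_node`, and optionally
#' `efficiency` and `replicate`.
#'
#' @param path File path.
#' @return A [bvsa_design()].
#' @export
read_design_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "target_node")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("design TSV is missing column(s): ", paste(missing, collapse = ", "))
  bvsa_design(d$experiment_id, d$target_node,
              efficiency = if ("efficiency" %in% names(d)) d$efficiency
                           else NA_real_,
              replicate = if ("replicate" %in% names(d)) d$replicate
                          else NA_integer_)
}

#' @param design A [bvsa_design()].
#' @rdname read_design_tsv
#' @export
write_design_tsv <- function(design, path) {
  d <- data.frame(experiment_id = design$experiment,
                  target_node = design$target,
                  efficiency = design$efficiency,
                  replicate = design$replicate)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a called network as SIF
#'
#' Simple interaction format: one line per called edge,
#' `source<TAB>influences<TAB>target`, where source -> target corresponds
#' to adjacency entry `A[target, source] = 1`.
#'
#' @param network A [threshold_edges()] result, or a binary adjacency with
#'   `A[i, j] = 1` meaning `j -> i`.
#' @param path File path.
#' @export
write_sif <- function(network, path) {
  A <- if (inherits(network, "bvsa_network")) network$A else as.matrix(network)
  edges <- which(A == 1, arr.ind = TRUE)
  nm <- rownames(A)
  lines <- sprintf("%s\tinfluences\t%s", nm[edges[, 2]], nm[edges[, 1]])
  writeLines(lines, path)
  invisible(path)
}

#' Persist Gibbs chain traces as columnar text
#'
#' One row per sweep: sweep index, configuration bits as a 0/1 string, log
#' posterior score. Chains are concatenated with a chain index column.
#'
#' @param traces List of [run_chain()] traces.
#' @param path File path.
#' @export
write_traces_tsv <- function(traces, path) {
  rows <- do.call(rbind, lapply(seq_along(traces), function(k) {
    tr <- traces[[k]]
    data.frame(chain = k, sweep = seq_len(nrow(tr$samples)),
               bits = apply(tr$samples, 1, paste, collapse = ""),
               log_score = tr$log_scores)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
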
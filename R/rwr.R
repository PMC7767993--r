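#' Random-walk-with-restart configuration
#'
#' @param restart Restart probability r in (0, 1]. The walker returns to the
#'   seed distribution with probability r at each step. Default 0.5.
#' @param tol Convergence tolerance: iteration stops when the L1 change of the
#'   probability vector falls below `tol`. Default 1e-10.
#' @param max_iter Iteration cap; reaching it triggers a warning. Default 10000.
#' @return An object of class `rwr_config`.
#' @export
rwr_config <- function(restart = 0.5, tol = 1e-10, max_iter = 10000L) {
  stopifnot(is.numeric(restart), restart > 0, restart <= 1,
            is.numeric(tol), tol > 0, max_iter >= 1)
  structure(list(restart = restart, tol = tol, max_iter = as.integer(max_iter)),
            class = "rwr_config")
}

# internal: degree-column-stochastic transition matrix (isolated nodes get
# zero columns; their walker mass is re-injected by the restart term)
transition_matrix <- function(net) {
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  deg <- Matrix::colSums(A)
  A %*% Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0))
}

#' Steady-state RWR scores
#'
#' Iterates p <- (1-r) W p + r p0 to its fixed point, where W is the
#' degree-column-normalized adjacency matrix and p0 is uniform over the seed
#' genes. Scores measure network proximity to the seeds.
#'
#' @param net An igraph network with named vertices.
#' @param seeds Non-empty character vector of seed genes, all in `net`.
#' @param config An [rwr_config].
#' @return Named numeric vector over all nodes; non-negative, sums to 1 within
#'   `10 * tol`; zero off the seeds' components.
#' @export
rwr_scores <- function(net, seeds, config = rwr_config()) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("empty seed set", call. = FALSE)
  nodes <- igraph::V(net)$name
  missing <- setdiff(seeds, nodes)
  if (length(missing))
    stop("seed gene(s) not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  p0 <- numeric(length(nodes))
  names(p0) <- nodes
  p0[seeds] <- 1 / length(seeds)
  r <- config$restart
  if (r == 1) return(p0)
  W <- transition_matrix(net)
  p <- p0
  for (it in seq_len(config$max_iter)) {
    step <- as.numeric(W %*% p)
    # dangling mass (zero columns of isolated nodes) restarts at the seeds,
    # keeping the distribution stochastic
    lost <- 1 - sum(step)
    p_new <- (1 - r) * (step + lost * p0) + r * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < config$tol) break
  }
  if (delta >= config$tol)
    warning(sprintf("RWR did not converge in %d iterations (L1 change %.3g)",
                    config$max_iter, delta), call. = FALSE)
  names(p) <- nodes
  p
}

#' Rank a gene universe by RWR proximity to seeds
#'
#' @inheritParams rwr_scores
#' @param universe Genes to rank (subset of `net` nodes); defaults to all.
#' @return Character vector: `universe` sorted by descending RWR score, ties
#'   broken lexicographically by symbol (deterministic).
#' @export
rank_by_rwr <- function(net, seeds, config = rwr_config(),
                        universe = igraph::V(net)$name) {
  universe <- unique(as.character(universe))
  missing <- setdiff(universe, igraph::V(net)$name)
  if (length(missing))
    stop("universe gene(s) not in network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  s <- rwr_scores(net, seeds, config)[universe]
  universe[order(-s, universe)]
}
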
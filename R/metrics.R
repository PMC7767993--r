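# Per-pair association scores: distances, overlap, cross-edge counting,
# gene-set expansion inside a module, and participation proportions.

# internal: shared distance-matrix workhorse. Unreachable entries (Inf) are
# excluded from the mean with a warning reporting the count; opt-in
# imputation replaces them by diameter + 1.
pair_distance <- function(net, from, to, fun = c("min", "all"),
                          impute_unreachable = FALSE) {
  fun <- match.arg(fun)
  from_m <- map_to_network(net, from)
  to_m <- map_to_network(net, to)
  if (length(from_m) == 0L || length(to_m) == 0L)
    stop("no mapped genes in one of the sets", call. = FALSE)
  D <- igraph::distances(net, v = from_m, to = to_m)
  vals <- if (fun == "min") apply(D, 1, min) else as.numeric(D)
  bad <- !is.finite(vals)
  if (any(bad)) {
    if (impute_unreachable) {
      vals[bad] <- igraph::diameter(net) + 1
      warning(sprintf("%d unreachable contribution(s) imputed as diameter+1",
                      sum(bad)), call. = FALSE)
    } else {
      warning(sprintf("%d unreachable contribution(s) excluded from the mean",
                      sum(bad)), call. = FALSE)
      vals <- vals[!bad]
    }
  }
  if (length(vals) == 0L) stop("all contributions unreachable", call. = FALSE)
  mean(vals)
}

#' Closest distance from set A to set S (DIcd)
#'
#' Mean, over mapped genes a of A, of the minimum hop distance to any mapped
#' gene of S. Genes in the overlap contribute 0. Smaller values mean a
#' stronger association.
#'
#' @param net igraph network.
#' @param A,S Gene sets ([gene_set] or character vectors); mapped onto `net`.
#' @param impute_unreachable If `TRUE`, unreachable contributions enter the
#'   mean as diameter + 1 instead of being excluded.
#' @return Non-negative number.
#' @export
closest_distance_AS <- function(net, A, S, impute_unreachable = FALSE) {
  pair_distance(net, A, S, "min", impute_unreachable)
}

#' Closest distance from set S to set A
#'
#' Symmetric counterpart of [closest_distance_AS()]: mean over mapped genes
#' of S of the minimum distance to A.
#' @inheritParams closest_distance_AS
#' @export
closest_distance_SA <- function(net, S, A, impute_unreachable = FALSE) {
  pair_distance(net, S, A, "min", impute_unreachable)
}

#' Mean pairwise shortest distance between two sets
#'
#' Mean of d(a, s) over all mapped pairs (double normalization by |A||S|).
#' @inheritParams closest_distance_AS
#' @export
shortest_distance <- function(net, A, S, impute_unreachable = FALSE) {
  pair_distance(net, A, S, "all", impute_unreachable)
}

#' Jaccard coefficient of two gene sets (DIoverlap)
#'
#' @param A,S Gene sets or character vectors; the union must be non-empty.
#' @return |A n S| / |A u S| in [0, 1].
#' @export
jaccard <- function(A, S) {
  a <- set_genes(A); s <- set_genes(S)
  u <- union(a, s)
  if (length(u) == 0L) stop("both sets empty", call. = FALSE)
  length(intersect(a, s)) / length(u)
}

#' Classify between-set interactions and compute DIconnectivity
#'
#' Partitions the graph's nodes into pure-A (A\\S), pure-S (S\\A), overlap
#' (A n S) and other, then counts the four between-set edge categories:
#' h1 pure-A--pure-S, h2 pure-S--overlap, h3 pure-A--overlap, h4
#' overlap--overlap. Edges within pure-A, within pure-S, or touching "other"
#' genes are never counted. The weighted score is h1 + h2 + h3 + 2*h4
#' (overlap--overlap edges carry weight 2).
#'
#' @param g igraph network (whole network or a module subgraph).
#' @param A,S Gene sets; intersected with the nodes of `g`.
#' @return Object of class `interaction_counts`: list with `h1`..`h4` and
#'   `weighted_score`.
#' @export
classify_interactions <- function(g, A, S) {
  a <- map_to_network(g, A); s <- map_to_network(g, S)
  el <- igraph::as_edgelist(g)
  cat_of <- function(v) {
    ina <- v %in% a; ins <- v %in% s
    ifelse(ina & ins, 3L, ifelse(ina, 1L, ifelse(ins, 2L, 0L)))
  }
  c1 <- cat_of(el[, 1]); c2 <- cat_of(el[, 2])
  lo <- pmin(c1, c2); hi <- pmax(c1, c2)
  h1 <- sum(lo == 1L & hi == 2L)
  h2 <- sum(lo == 2L & hi == 3L)
  h3 <- sum(lo == 1L & hi == 3L)
  h4 <- sum(lo == 3L & hi == 3L)
  structure(list(h1 = h1, h2 = h2, h3 = h3, h4 = h4,
                 weighted_score = h1 + h2 + h3 + 2 * h4),
            class = "interaction_counts")
}

#' @export
print.interaction_counts <- function(x, ...) {
  cat(sprintf("h1=%d h2=%d h3=%d h4=%d  DIconnectivity=%g\n",
              x$h1, x$h2, x$h3, x$h4, x$weighted_score))
  invisible(x)
}

#' Expand a mapped gene set inside a module (eDMN expansion)
#'
#' Runs RWR on the module subgraph seeded with the mapped genes and returns
#' the top `n = min(fold * |mapped|, |eMN|)` genes of the ranking (descending
#' score, ties lexicographic).
#'
#' @param mn A `module_network`.
#' @param mapped Non-empty subset of the module's expanded genes.
#' @param fold Expansion fold N.
#' @param config An [rwr_config].
#' @return Character vector of expanded genes (a superset ranking prefix).
#' @export
expand_gene_set <- function(mn, mapped, fold = 3, config = rwr_config()) {
  mapped <- unique(as.character(mapped))
  if (length(mapped) == 0L) stop("empty mapped gene set", call. = FALSE)
  if (!all(mapped %in% mn$expanded_genes))
    stop("mapped genes must lie inside the module", call. = FALSE)
  n <- min(floor(fold * length(mapped)), length(mn$expanded_genes))
  ranked <- rank_by_rwr(mn$graph, mapped, config, universe = mn$expanded_genes)
  ranked[seq_len(n)]
}

#' Proportion of each set's genes participating in the connectivity
#'
#' Fraction of mapped A-genes (resp. S-genes) incident to at least one
#' counted between-set edge (categories h1-h4 of [classify_interactions()]).
#'
#' @inheritParams classify_interactions
#' @return Named numeric vector `c(prop_A = ..., prop_S = ...)`.
#' @export
gene_participation <- function(g, A, S) {
  a <- map_to_network(g, A); s <- map_to_network(g, S)
  if (length(a) == 0L || length(s) == 0L)
    stop("no mapped genes in one of the sets", call. = FALSE)
  el <- igraph::as_edgelist(g)
  cat_of <- function(v) {
    ina <- v %in% a; ins <- v %in% s
    ifelse(ina & ins, 3L, ifelse(ina, 1L, ifelse(ins, 2L, 0L)))
  }
  c1 <- cat_of(el[, 1]); c2 <- cat_of(el[, 2])
  lo <- pmin(c1, c2); hi <- pmax(c1, c2)
  counted <- (lo == 1L & hi == 2L) | (lo >= 1L & hi == 3L)
  inc <- unique(c(el[counted, 1], el[counted, 2]))
  c(prop_A = length(intersect(a, inc)) / length(a),
    prop_S = length(intersect(s, inc)) / length(s))
}
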
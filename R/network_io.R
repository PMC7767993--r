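#' Read an undirected PPI network from a two-column edge list
#'
#' The first two whitespace/tab-separated tokens of each line are the edge
#' endpoints; extra columns are ignored; lines starting with `#` are comments.
#' Self-loops are dropped and duplicate (undirected) edges collapsed; counts
#' of dropped records are reported via [message()].
#'
#' @param path Path to the edge-list file.
#' @param uppercase If `TRUE`, gene symbols are uppercased on load. Default
#'   `FALSE`: symbols are case-sensitive opaque strings.
#' @return An undirected, simple [igraph][igraph::graph] with vertex `name`
#'   attributes (the package's network representation throughout).
#' @export
read_edge_list <- function(path, uppercase = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty edge list: ", path, call. = FALSE)
  ends <- matrix(NA_character_, nrow = length(idx), ncol = 2L)
  for (j in seq_along(idx)) {
    tok <- strsplit(trimws(lines[[idx[j]]]), "[ \t]+")[[1]]
    if (length(tok) < 2L)
      stop(sprintf("edge-list parse error at line %d: fewer than 2 columns",
                   idx[j]), call. = FALSE)
    ends[j, ] <- tok[1:2]
  }
  if (uppercase) ends[] <- toupper(ends)
  self <- ends[, 1] == ends[, 2]
  # self-loop endpoints stay in the graph as isolated nodes
  loop_nodes <- unique(ends[self, 1])
  ends_ok <- ends[!self, , drop = FALSE]
  key <- paste(pmin(ends_ok[, 1], ends_ok[, 2]),
               pmax(ends_ok[, 1], ends_ok[, 2]), sep = "\r")
  dup <- duplicated(key)
  g <- igraph::graph_from_edgelist(ends_ok[!dup, , drop = FALSE],
                                   directed = FALSE)
  extra <- setdiff(loop_nodes, igraph::V(g)$name)
  if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  if (sum(self) || sum(dup))
    message(sprintf("read_edge_list: dropped %d self-loop(s), %d duplicate edge(s)",
                    sum(self), sum(dup)))
  g
}

#' Write a network as a canonical two-column edge list
#'
#' Endpoints are sorted within each edge and lines sorted lexicographically,
#' so write/read round-trips are identity on canonicalized networks.
#'
#' @param net An igraph network with named vertices.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    o <- order(a, b)
    writeLines(paste(a[o], b[o], sep = "\t"), path)
  } else writeLines(character(0), path)
  invisible(path)
}

#' Largest connected component
#'
#' Induced subgraph on the largest component; when components tie in size the
#' one containing the lexicographically smallest gene symbol is taken.
#'
#' @param net An igraph network with named vertices.
#' @return The induced subgraph on the winning component.
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # tie-break: component holding the smallest symbol
    firsts <- vapply(best, function(k)
      min(igraph::V(net)$name[comp$membership == k]), character(1))
    best <- best[order(firsts)[1]]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Unweighted shortest-path distances from a set of sources
#'
#' Hop counts from each source gene to every node; unreachable pairs carry the
#' explicit sentinel `Inf` (never a large finite number).
#'
#' @param net An igraph network with named vertices.
#' @param sources Character vector of source genes; must all be in `net`.
#' @return Numeric matrix, rows = sources, columns = all nodes, entries = hop
#'   counts or `Inf`.
#' @export
bfs_distances <- function(net, sources) {
  sources <- unique(as.character(sources))
  missing <- setdiff(sources, igraph::V(net)$name)
  if (length(missing))
    stop("source gene(s) not in network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- igraph::distances(net, v = sources, to = igraph::V(net))
  colnames(d) <- igraph::V(net)$name
  d
}

# internal: map a gene set onto the network's node universe
map_to_network <- function(net, x) intersect(set_genes(x), igraph::V(net)$name)
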
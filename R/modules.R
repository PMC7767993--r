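#' Filter biological-process gene sets by size
#'
#' Keeps sets whose gene count lies in `[min_size, max_size]` (inclusive),
#' dropping very small and overly large functional sets before module
#' construction.
#'
#' @param bp_sets List of [gene_set] objects.
#' @param min_size,max_size Inclusive size bounds; defaults 30 and 500.
#' @return The filtered list.
#' @export
filter_bp_terms <- function(bp_sets, min_size = 30, max_size = 500) {
  n <- vapply(bp_sets, function(s) length(set_genes(s)), integer(1))
  bp_sets[n >= min_size & n <= max_size]
}

#' Build a modularized network (MN) from a BP gene set
#'
#' Maps the set's genes onto the reference network and takes the induced
#' subgraph. The result records both the base (BP-mapped) genes and the
#' expanded membership, which at this stage equals the base.
#'
#' @param net Reference igraph network.
#' @param bp A [gene_set] (provenance `"go_bp"`).
#' @return An object of class `module_network`: list with `bp_id`,
#'   `base_genes`, `expanded_genes`, `graph` (induced subgraph), `fold`, `cap`.
#' @export
build_mn <- function(net, bp) {
  base <- sort(map_to_network(net, bp))
  id <- if (inherits(bp, "gene_set")) bp$id else deparse(substitute(bp))
  if (length(base) == 0L)
    stop("no genes of BP '", id, "' map to the network", call. = FALSE)
  structure(list(bp_id = id,
                 base_genes = base,
                 expanded_genes = base,
                 graph = igraph::induced_subgraph(net, base),
                 fold = 1L, cap = NA_integer_),
            class = "module_network")
}

#' @export
print.module_network <- function(x, ...) {
  cat(sprintf("<module_network> %s: %d base genes, %d expanded, %d edges\n",
              x$bp_id, length(x$base_genes), length(x$expanded_genes),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Expand an MN into an eMN by seeded RWR
#'
#' Runs one RWR on the reference network seeded jointly with all base genes
#' and adds the top-ranked non-member genes until the membership reaches
#' `min(fold * |base|, cap)` genes, or until the seeds' components are
#' exhausted (then stops with a warning; score-0 off-component genes are
#' never added). The subgraph is re-induced on the expanded membership.
#'
#' @param net Reference igraph network (the same used to build `mn`).
#' @param mn A `module_network` from [build_mn()].
#' @param fold Expansion fold N >= 1.
#' @param cap Hard cap on the expanded size; default 500.
#' @param config An [rwr_config].
#' @return The expanded `module_network`.
#' @export
expand_mn <- function(net, mn, fold = 3, cap = 500, config = rwr_config()) {
  stopifnot(inherits(mn, "module_network"), fold >= 1)
  base <- mn$base_genes
  target <- min(floor(fold * length(base)), cap)
  expanded <- base
  if (target > length(base)) {
    s <- rwr_scores(net, base, config)
    cand <- setdiff(names(s)[s > 0], base)
    cand <- cand[order(-s[cand], cand)]
    need <- target - length(base)
    if (length(cand) < need) {
      warning(sprintf("module %s: component exhausted at %d genes (target %d)",
                      mn$bp_id, length(base) + length(cand), target),
              call. = FALSE)
      need <- length(cand)
    }
    expanded <- sort(c(base, cand[seq_len(need)]))
  }
  structure(list(bp_id = mn$bp_id,
                 base_genes = base,
                 expanded_genes = expanded,
                 graph = igraph::induced_subgraph(net, expanded),
                 fold = fold, cap = as.integer(cap)),
            class = "module_network")
}

#' Pair eligibility of a module
#'
#' A module is eligible for a (focal, disease) pair when strictly more than
#' `min_mapped` genes of each set map onto it. For eMN-based methods,
#' eligibility is evaluated on the parent MN's base genes (`on = "base"`);
#' DINet evaluates it on the expanded membership (`on = "expanded"`).
#'
#' @param mn A `module_network`.
#' @param A,S Gene sets (focal and disease).
#' @param min_mapped Strict lower bound; default 5 (i.e. at least 6 mapped).
#' @param on `"base"` or `"expanded"`.
#' @return Logical scalar.
#' @export
eligible_for_pair <- function(mn, A, S, min_mapped = 5,
                              on = c("base", "expanded")) {
  on <- match.arg(on)
  genes <- if (on == "base") mn$base_genes else mn$expanded_genes
  length(intersect(set_genes(A), genes)) > min_mapped &&
    length(intersect(set_genes(S), genes)) > min_mapped
}

#' Build the eMN catalog used by module-based methods
#'
#' Convenience wrapper: size-filters the BP library, builds each MN that maps
#' onto the network, and RWR-expands it.
#'
#' @param net Reference igraph network.
#' @param bp_sets List of [gene_set] objects.
#' @param fold Expansion fold; default 3.
#' @param cap Expansion cap; default 500.
#' @param min_size,max_size BP size filter bounds.
#' @param config An [rwr_config].
#' @return Named list of expanded `module_network` objects.
#' @export
build_emn_catalog <- function(net, bp_sets, fold = 3, cap = 500,
                              min_size = 30, max_size = 500,
                              config = rwr_config()) {
  bp_sets <- filter_bp_terms(bp_sets, min_size, max_size)
  out <- list()
  for (bp in bp_sets) {
    if (length(map_to_network(net, bp)) == 0L) next
    mn <- build_mn(net, bp)
    out[[mn$bp_id]] <- expand_mn(net, mn, fold = fold, cap = cap,
                                 config = config)
  }
  out
}
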
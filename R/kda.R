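# Key-connector analysis: dynamic neighborhood search (DNS) with
# hypergeometric enrichment and Bonferroni correction on an undirected
# network. On PPI networks the hits act as connector hubs, not directed
# regulators.

#' Per-gene DNS hypergeometric enrichment
#'
#' Builds the search subnet N_G of all nodes within `L` hops of the query
#' set G, then for every gene g in N_G and every layer h = 1..H tests the
#' <= h-hop neighborhood of g (in N_G, excluding g itself) for
#' overrepresentation of G-members with the hypergeometric upper tail
#' P(X >= k); the population is N_G minus g, so a gene is never part of its
#' own background. The gene's statistic is the minimum p over layers.
#'
#' @param net Undirected igraph network.
#' @param G Character vector (or [gene_set]) of query genes; the part mapped
#'   onto `net` must be non-empty.
#' @param L Subnet radius; default 2.
#' @param H Maximum neighborhood layer; default 2.
#' @return data.frame with one row per gene of N_G: `gene`, `p_raw`,
#'   `best_h`, `in_G`, and `n_h<k>`/`p_h<k>` columns per layer.
#' @export
kda_enrichment <- function(net, G, L = 2, H = 2) {
  g_all <- map_to_network(net, G)
  if (length(g_all) == 0L)
    stop("no query genes map onto the network", call. = FALSE)
  dG <- igraph::distances(net, v = g_all, to = igraph::V(net))
  ng_nodes <- igraph::V(net)$name[apply(dG, 2, min) <= L]
  sub <- igraph::induced_subgraph(net, ng_nodes)
  nodes <- igraph::V(sub)$name
  n <- length(nodes)
  D <- igraph::distances(sub)
  rownames(D) <- colnames(D) <- nodes
  in_g <- nodes %in% g_all
  n_succ_total <- sum(in_g)
  res <- data.frame(gene = nodes, p_raw = NA_real_, best_h = NA_integer_,
                    in_G = in_g, stringsAsFactors = FALSE)
  for (h in seq_len(H)) {
    res[[paste0("n_h", h)]] <- NA_integer_
    res[[paste0("p_h", h)]] <- NA_real_
  }
  for (i in seq_len(n)) {
    pop <- n - 1L
    succ <- n_succ_total - as.integer(in_g[i])
    best <- 1; besth <- NA_integer_
    for (h in seq_len(H)) {
      nb <- which(D[i, ] <= h & D[i, ] > 0)
      k <- sum(in_g[nb]); draws <- length(nb)
      p <- stats::phyper(k - 1, succ, pop - succ, draws, lower.tail = FALSE)
      res[[paste0("n_h", h)]][i] <- draws
      res[[paste0("p_h", h)]][i] <- p
      if (p < best || is.na(besth)) { best <- p; besth <- h }
    }
    res$p_raw[i] <- best; res$best_h[i] <- besth
  }
  res
}

#' Key connectors by dynamic neighborhood search
#'
#' Runs [kda_enrichment()] and Bonferroni-adjusts the per-gene minimum p over
#' the family of all tested genes (|N_G|, not H |N_G|: the min over layers is
#' each gene's single statistic). Genes with Bonferroni p <= `alpha` are key
#' connectors.
#'
#' @inheritParams kda_enrichment
#' @param alpha Bonferroni cutoff (inclusive); default 0.05.
#' @return data.frame of key connectors sorted by Bonferroni p ascending
#'   (`gene`, `best_h`, `p_raw`, `p_bonferroni`, `in_G`), with the complete
#'   tested table in attribute `"all_tested"`.
#' @export
key_connectors <- function(net, G, L = 2, H = 2, alpha = 0.05) {
  res <- kda_enrichment(net, G, L = L, H = H)
  res$p_bonferroni <- pmin(1, nrow(res) * res$p_raw)
  keep <- res[res$p_bonferroni <= alpha,
              c("gene", "best_h", "p_raw", "p_bonferroni", "in_G")]
  keep <- keep[order(keep$p_bonferroni, keep$gene), ]
  rownames(keep) <- NULL
  attr(keep, "all_tested") <- res
  keep
}
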
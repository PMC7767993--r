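# Which functional subnets carry a connection, how often, and how
# specifically: significant-eMN identification and the KF/AF/SP statistics.

#' Significant eMNs for one (focal, disease) connection
#'
#' Only eligible eMNs with positive observed eDMN weighted score enter. For
#' each, the focal genes are permuted within the eMN (`n_perm` draws, the
#' focal expansion recomputed per draw, the disease expansion held fixed),
#' the observed score is converted to a z-statistic and upper-tail normal p,
#' and BH adjustment runs across the connection's eMNs. eMNs with FDR <=
#' `fdr` (inclusive) are significant. An empty result is legitimate.
#'
#' @param A,S Focal and disease gene sets.
#' @param emns eMN catalog (named list of `module_network`).
#' @param fold eDMN expansion fold used for scoring.
#' @param n_perm Permutations per eMN; default 100.
#' @param fdr FDR cutoff (inclusive); default 0.05.
#' @param min_mapped Strict eligibility bound; default 5.
#' @param config An [rwr_config].
#' @param seed Run-level seed.
#' @return Character vector of significant eMN ids, with the full per-eMN
#'   table in attribute `"table"`.
#' @export
significant_emns <- function(A, S, emns, fold = 3, n_perm = 100, fdr = 0.05,
                             min_mapped = 5, config = rwr_config(),
                             seed = 1L) {
  a_all <- set_genes(A); s_all <- set_genes(S)
  rows <- list()
  for (m in emns) {
    if (!eligible_for_pair(m, a_all, s_all, min_mapped, on = "base")) next
    genes <- m$expanded_genes
    am <- intersect(a_all, genes); sm <- intersect(s_all, genes)
    if (length(am) == 0L || length(sm) == 0L) next
    es <- expand_gene_set(m, sm, fold, config)
    score_fn <- function(aset)
      classify_interactions(m$graph, expand_gene_set(m, aset, fold, config),
                            es)$weighted_score
    obs <- score_fn(am)
    if (obs <= 0) next
    rec <- permutation_null(score_fn, genes, am, n_perm = n_perm,
                            seed = derive_seed(seed, m$bp_id),
                            orientation = "greater")
    rows[[m$bp_id]] <- data.frame(emn_id = m$bp_id, score = obs, z = rec$z,
                                  p = rec$p, degenerate = rec$degenerate,
                                  stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- character(0)
    attr(out, "table") <- data.frame(emn_id = character(0), score = numeric(0),
                                     z = numeric(0), p = numeric(0),
                                     p_adj = numeric(0))
    return(out)
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- adjust_pvalues(tab$p, "BH")
  tab$significant <- tab$p_adj <= fdr
  rownames(tab) <- NULL
  out <- tab$emn_id[tab$significant]
  attr(out, "table") <- tab
  out
}

#' Per-eMN significance frequency across connections
#'
#' @param sig_table Named list: connection id -> character vector of
#'   significant eMN ids.
#' @return Named integer vector: eMN id -> number of connections in which it
#'   is significant (never-significant eMNs are absent).
#' @export
emn_frequency <- function(sig_table) {
  ids <- unlist(sig_table, use.names = FALSE)
  if (length(ids) == 0L) return(integer(0))
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}

#' Average eMN frequency of one connection
#'
#' Mean, over the connection's significant eMNs, of those eMNs' significance
#' frequencies across all connections (AF_conn).
#'
#' @param sig_table As in [emn_frequency()].
#' @param frequencies Output of [emn_frequency()] over the same table.
#' @param pair Connection id.
#' @return The mean frequency, or `NA` when the connection has no
#'   significant eMN.
#' @export
connection_af <- function(sig_table, frequencies, pair) {
  ids <- sig_table[[pair]]
  if (is.null(ids) || length(ids) == 0L) return(NA_real_)
  mean(frequencies[ids])
}

#' Specificity index SP = KF / AF
#'
#' KF is an eMN's significance frequency restricted to the related-disease
#' (DRD) connections, AF its frequency over all connections; their ratio in
#' (0, 1] measures how specifically the subnet carries related-disease
#' connections.
#'
#' @param KF,AF Positive counts with `KF <= AF`.
#' @return KF / AF.
#' @export
specificity_index <- function(KF, AF) {
  if (any(KF <= 0) || any(AF <= 0) || any(KF > AF))
    stop("require 0 < KF <= AF", call. = FALSE)
  KF / AF
}

#' eMN specificity records from a labelled significance table
#'
#' @param sig_table Named list: connection id -> significant eMN ids.
#' @param drd_pairs Character vector of connection ids labelled as related
#'   (the KF universe).
#' @return data.frame `emn_id`, `KF`, `AF`, `SP` for every eMN significant in
#'   at least one related connection.
#' @export
specificity_records <- function(sig_table, drd_pairs) {
  af <- emn_frequency(sig_table)
  kf <- emn_frequency(sig_table[intersect(names(sig_table), drd_pairs)])
  if (length(kf) == 0L)
    return(data.frame(emn_id = character(0), KF = integer(0),
                      AF = integer(0), SP = numeric(0)))
  data.frame(emn_id = names(kf), KF = unname(kf),
             AF = unname(af[names(kf)]),
             SP = specificity_index(unname(kf), unname(af[names(kf)])),
             stringsAsFactors = FALSE)
}

#' Split eMNs into specific and non-specific by SP threshold
#'
#' Strictly greater than the threshold counts as specific. Both lists are
#' sorted by KF descending, ties by eMN id.
#'
#' @param records data.frame with `emn_id`, `KF`, `AF`, `SP` (see
#'   [specificity_records()]).
#' @param sp_threshold SP cutoff (e.g. 0.3 for a T1D-style run, 0.2 for
#'   T2D-style).
#' @return List with elements `specific` and `non_specific`.
#' @export
classify_specific <- function(records, sp_threshold) {
  o <- order(-records$KF, records$emn_id)
  records <- records[o, ]
  rownames(records) <- NULL
  list(specific = records[records$SP > sp_threshold, ],
       non_specific = records[records$SP <= sp_threshold, ])
}
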
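# The ten method variants end to end: running-sum enrichment (DINet),
# expanded-set connectivity (eDMN), dispatch, ranking, fold sweeps.

#' Method names
#'
#' The ten scoring variants. Orientation is smaller-is-stronger for `DIcd`
#' and `DINet` (a minimum adjusted p-value), larger-is-stronger otherwise.
#' @export
diconnect_methods <- function() {
  c("DIcd",
    "DIoverlap-Whole", "DIoverlap-MN", "DIoverlap-eMN", "DIoverlap-eDMN",
    "DINet",
    "DIconnectivity-Whole", "DIconnectivity-MN", "DIconnectivity-eMN",
    "DIconnectivity-eDMN")
}

method_orientation <- function(method) {
  if (method %in% c("DIcd", "DINet")) "less" else "greater"
}

#' Running-sum enrichment score over a ranked gene list
#'
#' Walks the ranked list accumulating +(N-G)/G for each hit and -G/(N-G) for
#' each non-hit (N genes, G hits); the score is the peak (maximum prefix sum)
#' of the resulting curve. `form = "ks"` switches to the zero-sum
#' Kolmogorov-Smirnov increments +1/G and -1/(N-G).
#'
#' @param ranked Character vector: the ranked gene list.
#' @param hits Character vector of hit genes; must satisfy 0 < |hits| < N
#'   within the ranked universe.
#' @param form `"literal"` (default) or `"ks"`.
#' @return The peak running sum.
#' @export
gsea_running_score <- function(ranked, hits, form = c("literal", "ks")) {
  form <- match.arg(form)
  is_hit <- ranked %in% hits
  N <- length(ranked); G <- sum(is_hit)
  if (G == 0L || G == N)
    stop("hits must be a non-empty proper subset of the ranked list",
         call. = FALSE)
  inc <- if (form == "literal") {
    ifelse(is_hit, (N - G) / G, -G / (N - G))
  } else {
    ifelse(is_hit, 1 / G, -1 / (N - G))
  }
  max(cumsum(inc))
}

# internal: constructor for a per-pair result row
connection_score <- function(disease_id, method, score, n_modules_used = NA_integer_,
                             detail = NULL) {
  structure(list(disease_id = disease_id, method = method, score = score,
                 n_modules_used = n_modules_used, detail = detail),
            class = "connection_score")
}

#' DINet score for one pair
#'
#' Per eligible eMN (strictly more than `min_mapped` genes of each set mapped
#' on the expanded membership): two RWR rankings are computed, seeded with the
#' mapped disease genes and the mapped focal genes respectively. ES1 scores
#' the focal hits on the disease-seeded ranking, ES2 the disease hits on the
#' focal-seeded ranking, and ES_beta = beta ES1 + (1-beta) ES2. Significance
#' comes from permuting the focal genes within the eMN (`n_perm` draws,
#' re-running the focal-seeded RWR for each draw), a z-score against the
#' permutation null, an upper-tail normal p, and BH adjustment across the
#' pair's eMNs. The pair score is the minimum adjusted p-value (smaller is
#' stronger).
#'
#' @param A Focal gene set. @param S Disease gene set.
#' @param emns Named list of `module_network` objects (the eMN catalog).
#' @param beta Weight in (0, 1) on ES1; default 0.5.
#' @param n_perm Permutations per eMN; default 100.
#' @param min_mapped Strict eligibility bound; default 5.
#' @param config An [rwr_config].
#' @param seed Run-level seed; per-eMN substreams derive via [derive_seed()].
#' @param gsea_form Passed to [gsea_running_score()].
#' @return A `connection_score` (score = min adjusted p, or `NA` when no eMN
#'   is eligible) whose `detail` holds the per-eMN table.
#' @export
dinet_pair <- function(A, S, emns, beta = 0.5, n_perm = 100, min_mapped = 5,
                       config = rwr_config(), seed = 1L,
                       gsea_form = "literal") {
  stopifnot(beta > 0, beta < 1)
  a_all <- set_genes(A); s_all <- set_genes(S)
  rows <- list()
  for (m in emns) {
    if (!eligible_for_pair(m, a_all, s_all, min_mapped, on = "expanded")) next
    genes <- m$expanded_genes
    am <- intersect(a_all, genes); sm <- intersect(s_all, genes)
    if (length(am) >= length(genes) || length(sm) >= length(genes)) next
    rank_S <- rank_by_rwr(m$graph, sm, config, universe = genes)
    rank_A <- rank_by_rwr(m$graph, am, config, universe = genes)
    es1 <- gsea_running_score(rank_S, am, gsea_form)
    es2 <- gsea_running_score(rank_A, sm, gsea_form)
    es_obs <- beta * es1 + (1 - beta) * es2
    score_fn <- function(aperm) {
      e1 <- gsea_running_score(rank_S, aperm, gsea_form)
      rk <- rank_by_rwr(m$graph, aperm, config, universe = genes)
      e2 <- gsea_running_score(rk, sm, gsea_form)
      beta * e1 + (1 - beta) * e2
    }
    rec <- permutation_null(score_fn, genes, am, n_perm = n_perm,
                            seed = derive_seed(seed, m$bp_id),
                            orientation = "greater")
    rows[[m$bp_id]] <- data.frame(emn_id = m$bp_id, es1 = es1, es2 = es2,
                                  es_beta = es_obs, z = rec$z, p = rec$p,
                                  stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(connection_score(id_of(S), "DINet", NA_real_, 0L))
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- adjust_pvalues(tab$p, "BH")
  connection_score(id_of(S), "DINet", min(tab$p_adj), nrow(tab), detail = tab)
}

id_of <- function(x) if (inherits(x, "gene_set")) x$id else "set"

#' DIconnectivity-eDMN score for one pair
#'
#' Per eligible eMN (eligibility from the parent MN's base genes), both
#' mapped gene sets are RWR-expanded inside the module ([expand_gene_set()],
#' top `min(fold |mapped|, |eMN|)` genes each) and the weighted between-set
#' edge count is taken on the eMN subgraph. The pair score is the mean over
#' eMNs with positive weighted score; with no positive module the score is 0
#' and `n_modules_used` 0.
#'
#' @inheritParams dinet_pair
#' @param fold Gene-set expansion fold N; default 3.
#' @param include_zero If `TRUE`, zero-score eligible eMNs enter the mean.
#' @return A `connection_score` with per-eMN detail.
#' @export
diconnectivity_edmn_pair <- function(A, S, emns, fold = 3, min_mapped = 5,
                                     config = rwr_config(),
                                     include_zero = FALSE) {
  a_all <- set_genes(A); s_all <- set_genes(S)
  ids <- character(0); vals <- numeric(0)
  for (m in emns) {
    if (!eligible_for_pair(m, a_all, s_all, min_mapped, on = "base")) next
    genes <- m$expanded_genes
    am <- intersect(a_all, genes); sm <- intersect(s_all, genes)
    if (length(am) == 0L || length(sm) == 0L) next
    ea <- expand_gene_set(m, am, fold, config)
    es <- expand_gene_set(m, sm, fold, config)
    ids <- c(ids, m$bp_id)
    vals <- c(vals, classify_interactions(m$graph, ea, es)$weighted_score)
  }
  use <- if (include_zero) rep(TRUE, length(vals)) else vals > 0
  score <- if (any(use)) mean(vals[use]) else 0
  connection_score(id_of(S), "DIconnectivity-eDMN", score, sum(use),
                   detail = if (length(ids))
                     data.frame(emn_id = ids, weighted_score = vals,
                                stringsAsFactors = FALSE))
}

#' Score one (focal, disease) pair with any of the ten methods
#'
#' Whole-network variants use the full reference network; MN variants average
#' the per-module statistic over eligible modules' base memberships and
#' base-induced subgraphs; eMN variants do the same on the expanded
#' memberships (eligibility still from the parent MN); eDMN variants expand
#' the mapped sets inside each module first. `DIcd` runs on the whole
#' network; `DINet` delegates to [dinet_pair()].
#'
#' @param method One of [diconnect_methods()].
#' @param A,S Gene sets (focal, disease).
#' @param net Reference igraph network.
#' @param modules Named list of `module_network` objects (expanded); required
#'   by all MN/eMN/eDMN variants and DINet.
#' @param fold eDMN gene-set expansion fold.
#' @param beta DINet ES weight.
#' @param n_perm DINet permutations.
#' @param min_mapped Strict eligibility bound.
#' @param config An [rwr_config].
#' @param seed Run-level seed (DINet permutations).
#' @return A `connection_score`.
#' @export
score_pair <- function(method, A, S, net, modules = NULL, fold = 3,
                       beta = 0.5, n_perm = 100, min_mapped = 5,
                       config = rwr_config(), seed = 1L) {
  if (!method %in% diconnect_methods())
    stop("unknown method: ", method, call. = FALSE)
  a_all <- set_genes(A); s_all <- set_genes(S)

  module_mean <- function(stat_fn, on) {
    vals <- numeric(0)
    for (m in modules) {
      if (!eligible_for_pair(m, a_all, s_all, min_mapped, on = "base")) next
      genes <- if (on == "base") m$base_genes else m$expanded_genes
      g <- if (on == "base") igraph::induced_subgraph(net, genes) else m$graph
      vals <- c(vals, stat_fn(m, g, intersect(a_all, genes),
                              intersect(s_all, genes)))
    }
    if (length(vals) == 0L)
      connection_score(id_of(S), method, NA_real_, 0L)
    else
      connection_score(id_of(S), method, mean(vals), length(vals))
  }

  switch(method,
    "DIcd" = connection_score(id_of(S), method,
                              closest_distance_AS(net, a_all, s_all)),
    "DIoverlap-Whole" = connection_score(id_of(S), method,
      jaccard(intersect(a_all, igraph::V(net)$name),
              intersect(s_all, igraph::V(net)$name))),
    "DIoverlap-MN" = module_mean(function(m, g, am, sm) jaccard(am, sm), "base"),
    "DIoverlap-eMN" = module_mean(function(m, g, am, sm) jaccard(am, sm),
                                  "expanded"),
    "DIoverlap-eDMN" = module_mean(function(m, g, am, sm) {
      if (length(am) == 0L || length(sm) == 0L) return(0)
      jaccard(expand_gene_set(m, am, fold, config),
              expand_gene_set(m, sm, fold, config))
    }, "expanded"),
    "DINet" = dinet_pair(A, S, modules, beta = beta, n_perm = n_perm,
                         min_mapped = min_mapped, config = config,
                         seed = seed),
    "DIconnectivity-Whole" = connection_score(id_of(S), method,
      classify_interactions(net, a_all, s_all)$weighted_score),
    "DIconnectivity-MN" = module_mean(function(m, g, am, sm)
      classify_interactions(g, am, sm)$weighted_score, "base"),
    "DIconnectivity-eMN" = module_mean(function(m, g, am, sm)
      classify_interactions(g, am, sm)$weighted_score, "expanded"),
    "DIconnectivity-eDMN" = {
      cs <- diconnectivity_edmn_pair(A, S, modules, fold = fold,
                                     min_mapped = min_mapped, config = config)
      cs$method <- method
      cs
    })
}

#' Rank a disease panel from one method's scores
#'
#' Converts the panel's scores into z-statistics against the panel's own
#' score distribution ([zscore_over_panel()]), flips the tail for
#' smaller-is-stronger methods, flags significance at p < `alpha`, and sorts
#' by the method's orientation (strongest association first).
#'
#' @param scores Named numeric vector (disease -> score) of one method for
#'   one focal set, length >= 3.
#' @param method The method that produced the scores (fixes orientation).
#' @param alpha Significance level; default 0.05.
#' @return data.frame `disease`, `score`, `z`, `p`, `significant`, `rank`.
#' @export
rank_diseases <- function(scores, method, alpha = 0.05) {
  if (!method %in% diconnect_methods())
    stop("unknown method: ", method, call. = FALSE)
  tab <- zscore_over_panel(scores, alpha)
  if (method_orientation(method) == "less") {
    tab$p <- stats::pnorm(tab$z, lower.tail = TRUE)
    tab$significant <- tab$p < alpha
    tab <- tab[order(tab$score, tab$disease), ]
  } else {
    tab <- tab[order(-tab$score, tab$disease), ]
  }
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Sweep the eDMN expansion fold and report AUC per fold
#'
#' Scores every (focal, disease) pair with DIconnectivity-eDMN at each fold
#' and evaluates the ranking against binary labels with [auc_roc()].
#'
#' @param A Focal gene set.
#' @param diseases Named list of disease gene sets.
#' @param emns eMN catalog.
#' @param labels Named logical vector (disease id -> is related).
#' @param folds Integer vector of folds to test; default 1:10.
#' @param min_mapped Strict eligibility bound.
#' @param config An [rwr_config].
#' @return data.frame `fold`, `auc`, with the argmax fold in attribute
#'   `"best_fold"`.
#' @export
sweep_fold <- function(A, diseases, emns, labels, folds = 1:10,
                       min_mapped = 5, config = rwr_config()) {
  aucs <- vapply(folds, function(f) {
    sc <- vapply(diseases, function(S)
      diconnectivity_edmn_pair(A, S, emns, fold = f, min_mapped = min_mapped,
                               config = config)$score, numeric(1))
    auc_roc(sc, labels[names(sc)], orientation = "larger")
  }, numeric(1))
  out <- data.frame(fold = folds, auc = aucs)
  attr(out, "best_fold") <- folds[which.max(aucs)]
  out
}
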
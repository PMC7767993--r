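#' Score a disease panel against a focal gene set on a PPI network
#'
#' The package's central fitting function. Builds the module catalog (when
#' the chosen method needs one), scores every disease in the panel against
#' the focal set, converts the scores to panel z-statistics with one-sided
#' p-values, and returns a classed result with `print`, `summary` and `plot`
#' methods. When truth labels are supplied the rank-based AUC is attached.
#'
#' @param net Reference igraph network (use
#'   [largest_connected_component()] first, as distances are only defined
#'   within a component).
#' @param focal Focal [gene_set] (e.g. a diabetes gene set).
#' @param diseases Named list of disease [gene_set]s (the panel), length >= 3.
#' @param bp_sets Named list of GO-BP [gene_set]s; required by all module
#'   methods, ignored by `DIcd`, `DIoverlap-Whole`, `DIconnectivity-Whole`.
#' @param method One of [diconnect_methods()]; default
#'   `"DIconnectivity-eDMN"`, the best-performing variant.
#' @param fold Expansion fold N for eMN construction and eDMN set expansion;
#'   default 3.
#' @param cap eMN size cap; default 500.
#' @param beta DINet enrichment weight in (0, 1); default 0.5.
#' @param n_perm DINet permutations per eMN; default 100.
#' @param min_mapped Strict module-eligibility bound; default 5.
#' @param config An [rwr_config].
#' @param seed Run-level seed for permutation substreams; default 1.
#' @param labels Optional named logical vector of truth labels for AUC.
#' @param alpha Significance level for the ranking flag; default 0.05.
#' @param modules Optional pre-built eMN catalog (overrides `bp_sets`),
#'   e.g. from [build_emn_catalog()], to reuse across methods or folds.
#' @return An object of class `diconnect`: list with `scores` (the ranked
#'   data.frame), `method`, `modules` (catalog or NULL), `auc`, `config`,
#'   `call`.
#' @examples
#' sim <- generate_synthetic(synthetic_spec(n_genes = 300, n_modules = 6,
#'   n_drd = 2, n_nondrd = 4, seed = 7))
#' fit <- diconnect(sim$network, sim$focal, sim$diseases, sim$bp_sets,
#'                  method = "DIoverlap-MN", labels = sim$labels)
#' fit
#' @export
diconnect <- function(net, focal, diseases, bp_sets = NULL,
                      method = "DIconnectivity-eDMN",
                      fold = 3, cap = 500, beta = 0.5, n_perm = 100,
                      min_mapped = 5, config = rwr_config(), seed = 1L,
                      labels = NULL, alpha = 0.05, modules = NULL) {
  if (!method %in% diconnect_methods())
    stop("unknown method: ", method, call. = FALSE)
  if (length(diseases) < 3L)
    stop("need a panel of at least 3 diseases", call. = FALSE)
  if (is.null(names(diseases)))
    names(diseases) <- vapply(diseases, id_of, character(1))
  needs_modules <- !method %in%
    c("DIcd", "DIoverlap-Whole", "DIconnectivity-Whole")
  if (needs_modules && is.null(modules)) {
    if (is.null(bp_sets))
      stop("method ", method, " requires bp_sets or a prebuilt module catalog",
           call. = FALSE)
    modules <- build_emn_catalog(net, bp_sets, fold = fold, cap = cap,
                                 config = config)
  }
  cs <- lapply(names(diseases), function(d)
    score_pair(method, focal, diseases[[d]], net, modules, fold = fold,
               beta = beta, n_perm = n_perm, min_mapped = min_mapped,
               config = config, seed = derive_seed(seed, d)))
  scores <- vapply(cs, function(x) x$score, numeric(1))
  names(scores) <- names(diseases)
  n_used <- vapply(cs, function(x) as.integer(x$n_modules_used), integer(1))
  names(n_used) <- names(diseases)
  # unscorable pairs (no eligible module): neutral worst-case fill so the
  # panel z-machinery stays defined
  fill <- if (method_orientation(method) == "less") 1 else 0
  scores[is.na(scores)] <- fill
  ranking <- tryCatch(rank_diseases(scores, method, alpha),
                      error = function(e) {
                        tab <- data.frame(disease = names(scores),
                                          score = unname(scores),
                                          z = NA_real_, p = NA_real_,
                                          significant = NA,
                                          stringsAsFactors = FALSE)
                        tab$rank <- rank(if (method_orientation(method) == "less")
                          tab$score else -tab$score, ties.method = "min")
                        tab
                      })
  ranking$n_modules_used <- n_used[ranking$disease]
  auc <- if (!is.null(labels))
    auc_roc(scores, labels[names(scores)],
            orientation = if (method_orientation(method) == "less")
              "smaller" else "larger")
  structure(list(scores = ranking, method = method, modules = modules,
                 auc = auc, focal_id = id_of(focal),
                 config = list(fold = fold, cap = cap, beta = beta,
                               n_perm = n_perm, min_mapped = min_mapped,
                               rwr = config, seed = seed, alpha = alpha),
                 call = match.call()),
            class = "diconnect")
}

#' @export
print.diconnect <- function(x, ...) {
  cat(sprintf("Disease panel connectivity: %s vs %d diseases (%s)\n",
              x$focal_id, nrow(x$scores), x$method))
  if (!is.null(x$modules))
    cat(sprintf("  module catalog: %d eMNs (fold %g, cap %d)\n",
                length(x$modules), x$config$fold, x$config$cap))
  if (!is.null(x$auc)) cat(sprintf("  AUC vs labels: %.3f\n", x$auc))
  nsig <- sum(x$scores$significant, na.rm = TRUE)
  cat(sprintf("  significant at p < %g: %d\n", x$config$alpha, nsig))
  cat("Top of ranking:\n")
  print(utils::head(x$scores, 5), row.names = FALSE)
  invisible(x)
}

#' @export
summary.diconnect <- function(object, ...) {
  structure(list(fit = object), class = "summary.diconnect")
}

#' @export
print.summary.diconnect <- function(x, ...) {
  print(x$fit)
  cat("\nFull ranking:\n")
  print(x$fit$scores, row.names = FALSE)
  invisible(x)
}

#' Plot a disease-panel connectivity ranking
#'
#' Dot chart of per-disease scores in rank order; significant diseases are
#' drawn filled.
#'
#' @param x A `diconnect` object. @param ... Passed to [graphics::dotchart()].
#' @export
plot.diconnect <- function(x, ...) {
  tab <- x$scores[rev(seq_len(nrow(x$scores))), ]
  pch <- ifelse(isTRUE(tab$significant) | tab$significant %in% TRUE, 19, 1)
  graphics::dotchart(tab$score, labels = tab$disease, pch = pch,
                     xlab = paste(x$method, "score"),
                     main = paste(x$focal_id, "panel ranking"), ...)
  invisible(x)
}
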
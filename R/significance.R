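# Permutation nulls, z-scores, normal-tail p-values and multiple-testing
# adjustment shared by DINet, DIconnectivity-eDMN and the eMN significance
# analysis.

#' Derive a reproducible substream seed from a run seed and a unit id
#'
#' Stable string hash combined with the run-level seed, so batch runs over
#' many (pair, eMN) units are reproducible and order-independent. Always
#' below 2^31.
#'
#' @param run_seed Integer run-level seed.
#' @param unit_id Character id of the unit (e.g. `"T1D|asthma|GO:0016055"`).
#' @return Integer seed.
#' @export
derive_seed <- function(run_seed, unit_id) {
  h <- 0
  for (x in utf8ToInt(as.character(unit_id)))
    h <- (h * 31 + x) %% 2147483629
  as.integer((h + as.numeric(run_seed) * 7919) %% 2147483629)
}

#' Permutation null and z-score for a module-level score
#'
#' Draws `n_perm` replacement gene sets of size `|A_mapped|` uniformly
#' without replacement from the module's gene universe ("permute the focal
#' genes in the eMN"), recomputes the score for each, fits the null mean and
#' sd, and converts the observed score to a z-statistic with a one-sided
#' normal-tail p-value (upper tail by default; lower tail for scores whose
#' orientation is smaller-is-stronger, such as DIcd).
#'
#' A degenerate null (sd = 0) yields p = 1 with a flag rather than an error,
#' so batch runs over thousands of modules complete.
#'
#' @param score_fn Function taking a character vector of genes and returning
#'   one number.
#' @param universe Gene universe to resample from: a `module_network` (its
#'   expanded genes) or a character vector.
#' @param A_mapped Observed focal gene set (subset of the universe).
#' @param n_perm Number of permutations, >= 2; default 100.
#' @param seed Integer seed for the permutation stream.
#' @param orientation `"greater"` (larger score is stronger) or `"less"`.
#' @return Object of class `significance_record`: list with `observed`,
#'   `null_mean`, `null_sd`, `z`, `p`, `p_empirical`, `degenerate`, `n_perm`,
#'   `seed`.
#' @export
permutation_null <- function(score_fn, universe, A_mapped, n_perm = 100,
                             seed = 1L, orientation = c("greater", "less")) {
  orientation <- match.arg(orientation)
  if (inherits(universe, "module_network")) universe <- universe$expanded_genes
  universe <- unique(as.character(universe))
  A_mapped <- unique(as.character(A_mapped))
  stopifnot(n_perm >= 2, length(A_mapped) >= 1)
  if (!all(A_mapped %in% universe))
    stop("A_mapped must be a subset of the resampling universe", call. = FALSE)
  observed <- score_fn(A_mapped)
  null <- numeric(n_perm)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  for (i in seq_len(n_perm))
    null[i] <- score_fn(sample(universe, length(A_mapped)))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  m <- mean(null); sdv <- stats::sd(null)
  degenerate <- !is.finite(sdv) || sdv == 0
  if (degenerate) {
    z <- NA_real_; p <- 1
  } else {
    z <- (observed - m) / sdv
    p <- stats::pnorm(z, lower.tail = (orientation == "less"))
  }
  cmp <- if (orientation == "greater") null >= observed else null <= observed
  structure(list(observed = observed, null_mean = m, null_sd = sdv,
                 z = z, p = p,
                 p_empirical = (1 + sum(cmp)) / (n_perm + 1),
                 degenerate = degenerate,
                 n_perm = n_perm, seed = seed, orientation = orientation),
            class = "significance_record")
}

#' @export
print.significance_record <- function(x, ...) {
  cat(sprintf("observed %.4g | null %.4g +/- %.4g | z %.3f | p %.4g%s\n",
              x$observed, x$null_mean, x$null_sd,
              if (is.na(x$z)) NA else x$z, x$p,
              if (x$degenerate) " [degenerate null]" else ""))
  invisible(x)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (FDR) or Bonferroni `min(1, n p)`,
#' order-preserving with the original indexing.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = method)
}

#' Panel z-scores for disease ranking
#'
#' Standardizes each disease's score against the mean and sd of the whole
#' panel's score distribution and attaches an upper-tail normal p-value and a
#' significance flag at p < 0.05.
#'
#' @param scores Named numeric vector (disease -> score), length >= 3 with
#'   positive sd.
#' @param alpha Significance level for the flag; default 0.05.
#' @return data.frame with columns `disease`, `score`, `z`, `p`,
#'   `significant`.
#' @export
zscore_over_panel <- function(scores, alpha = 0.05) {
  if (length(scores) < 3L) stop("need at least 3 diseases", call. = FALSE)
  sdv <- stats::sd(scores)
  if (!is.finite(sdv) || sdv == 0)
    stop("zero variance across the panel", call. = FALSE)
  z <- (scores - mean(scores)) / sdv
  p <- stats::pnorm(z, lower.tail = FALSE)
  data.frame(disease = names(scores), score = unname(scores),
             z = unname(z), p = unname(p), significant = unname(p < alpha),
             stringsAsFactors = FALSE)
}
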
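# Literature-Jaccard labelling, rank AUC, and readers for precomputed
# PubMed-ID lists. PubMed retrieval itself is out of scope: the co-occurrence
# formula consumes ID lists from disk.

#' Read a PubMed-ID list (one id per line)
#'
#' @param path Path to a text file, one record id per line; blank lines and
#'   `#` comments skipped.
#' @return Character vector of unique ids.
#' @export
read_pmid_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Literature co-occurrence Jaccard
#'
#' Jaccard coefficient between the PubMed-ID sets of a disease and of the
#' focal disease: shared literature over combined literature.
#'
#' @param ids_disease,ids_focal Character (or integer) vectors of record ids;
#'   the union must be non-empty.
#' @return Number in [0, 1].
#' @export
literature_jaccard <- function(ids_disease, ids_focal) {
  a <- unique(as.character(ids_disease)); b <- unique(as.character(ids_focal))
  u <- union(a, b)
  if (length(u) == 0L) stop("both id sets empty", call. = FALSE)
  length(intersect(a, b)) / length(u)
}

#' Label diseases as related via anchor-derived Jaccard threshold
#'
#' The threshold is the minimum literature Jaccard over a list of anchor
#' diseases known to be related; every disease strictly above the threshold
#' is labelled related, and the anchors themselves always are.
#'
#' @param jaccards Named numeric vector: disease -> literature Jaccard.
#' @param anchor_diseases Character vector of anchor names, all present in
#'   `jaccards` (e.g. `c("diabetic nephropathy", "obesity",
#'   "bacterial infection")`).
#' @return data.frame `disease`, `jaccard`, `is_drd`, `threshold`.
#' @export
annotate_drd <- function(jaccards, anchor_diseases) {
  missing <- setdiff(anchor_diseases, names(jaccards))
  if (length(missing))
    stop("anchor disease(s) missing from the map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  thr <- min(jaccards[anchor_diseases])
  is_drd <- jaccards > thr
  is_drd[anchor_diseases] <- TRUE
  data.frame(disease = names(jaccards), jaccard = unname(jaccards),
             is_drd = unname(is_drd), threshold = thr,
             stringsAsFactors = FALSE)
}

#' Rank-based ROC AUC
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative under the method's score, ties counting one half
#' (Mann-Whitney form). `orientation = "smaller"` treats smaller scores as
#' stronger (DIcd, DINet).
#'
#' @param scores Named numeric vector of scores.
#' @param labels Logical vector (same names/order) with both classes present.
#' @param orientation `"larger"` (default) or `"smaller"`.
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(scores, labels, orientation = c("larger", "smaller")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  if (length(labels) != length(scores) || any(is.na(labels)))
    stop("labels must align with scores", call. = FALSE)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("both classes must be present", call. = FALSE)
  s <- if (orientation == "smaller") -scores else scores
  r <- rank(s)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}
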
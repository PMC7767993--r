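#' Construct a gene set
#'
#' A gene set is a named collection of unique gene symbols with a provenance
#' tag ("disease", "go_bp", ...). Gene symbols are case-sensitive opaque
#' strings; no identifier mapping is performed.
#'
#' @param id Unique identifier of the set within its library.
#' @param genes Character vector of gene symbols; duplicates are dropped.
#' @param name Human-readable description (defaults to `id`).
#' @param type Provenance tag, e.g. `"disease"` or `"go_bp"`.
#' @return An object of class `gene_set`: a list with elements `id`, `name`,
#'   `genes` (unique, sorted) and `type`.
#' @export
gene_set <- function(id, genes, name = id, type = "disease") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L)
    stop("gene set '", id, "' has no genes", call. = FALSE)
  structure(list(id = id, name = name, genes = sort(genes), type = type),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s]: %d genes\n", x$id, x$type, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

# Accept either a gene_set or a plain character vector of symbols.
set_genes <- function(x) {
  if (inherits(x, "gene_set")) x$genes else unique(as.character(x))
}

#' Read a GMT gene-set library
#'
#' Broad-dialect GMT: one set per line, tab-separated
#' `id <TAB> description <TAB> gene <TAB> gene ...`. Within-line duplicate
#' genes are deduplicated; empty gene fields are skipped with a warning.
#'
#' @param path Path to a GMT file.
#' @param type Provenance tag assigned to every set (`"disease"` or `"go_bp"`).
#' @return A named list of [gene_set] objects (names are the set ids).
#' @export
read_gmt <- function(path, type = "disease") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i),
           call. = FALSE)
    genes <- fields[-(1:2)]
    if (any(!nzchar(genes))) {
      warning(sprintf("line %d (%s): %d empty gene field(s) skipped",
                      i, fields[[1]], sum(!nzchar(genes))), call. = FALSE)
      genes <- genes[nzchar(genes)]
    }
    if (length(genes) == 0L)
      stop(sprintf("GMT parse error at line %d: no genes", i), call. = FALSE)
    ids[[i]] <- fields[[1]]
    sets[[i]] <- gene_set(fields[[1]], genes, name = fields[[2]], type = type)
  }
  if (anyDuplicated(ids))
    stop("duplicate set ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(sets) <- ids
  sets
}

#' Write a gene-set library to GMT
#'
#' @param sets Named list of [gene_set] objects.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$id, s$name, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Merge several gene sets into one
#'
#' Union of member genes under a new id, as when pooling upregulated and
#' downregulated genes of the same disease term.
#'
#' @param sets Non-empty list of [gene_set] objects (or character vectors).
#' @param new_id Identifier for the merged set.
#' @param type Provenance tag of the result.
#' @return A [gene_set] containing the union.
#' @export
merge_gene_sets <- function(sets, new_id, type = "disease") {
  if (length(sets) == 0L) stop("cannot merge an empty list of gene sets",
                               call. = FALSE)
  gene_set(new_id, unique(unlist(lapply(sets, set_genes))), type = type)
}
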
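# Seeded synthetic interactome with planted functional modules and disease
# gene sets of controllable overlap and cross-edge density. Stands in for a
# real interactome and curated gene-set libraries so every pipeline runs and
# is testable offline.

#' Specification for a synthetic benchmark instance
#'
#' Defaults are the package's benchmark conditions: a 2000-gene
#' preferential-attachment backbone (heavy-tailed degrees, as in real
#' interactomes), 40 planted modules of 40-60 genes with elevated internal
#' density, a 150-gene focal set concentrated in 8 of the modules, 10 planted
#' related diseases sharing 20% of their genes with the focal set inside
#' common modules plus 3x cross-edge enrichment, and 40 size-matched random
#' non-related sets.
#'
#' @param n_genes Number of genes. @param pa_m Edges added per backbone node.
#' @param n_modules Number of planted modules.
#' @param module_size Length-2 inclusive size range of a module.
#' @param module_degree Extra internal mean degree added inside each module.
#' @param n_focal_modules Modules the focal set concentrates in.
#' @param focal_size,disease_size Gene-set sizes.
#' @param n_drd,n_nondrd Numbers of related / unrelated disease sets.
#' @param modules_per_drd Focal modules each related set shares.
#' @param overlap_frac Fraction of a related set drawn from the focal set.
#' @param cross_enrichment Multiplier on focal-disease cross edges inside
#'   shared modules; 1 adds nothing (pure null together with
#'   `overlap_frac = 0`).
#' @param seed Integer seed; the instance is fully determined by it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000, pa_m = 2, n_modules = 40,
                           module_size = c(40, 60), module_degree = 4,
                           n_focal_modules = 8, focal_size = 150,
                           disease_size = 120, n_drd = 10, n_nondrd = 40,
                           modules_per_drd = 4, overlap_frac = 0.2,
                           cross_enrichment = 3, seed = 1L) {
  stopifnot(n_genes > 0, n_modules > 0, n_drd > 0, n_nondrd > 0,
            overlap_frac >= 0, overlap_frac <= 1, cross_enrichment >= 1,
            length(module_size) == 2L, module_size[1] <= module_size[2],
            n_focal_modules <= n_modules, modules_per_drd <= n_focal_modules)
  if (module_size[2] > n_genes)
    stop("module larger than the graph", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic benchmark instance
#'
#' Builds a connected preferential-attachment backbone, plants modules as
#' gene subsets with extra internal edges, draws the focal set from the
#' focal modules, builds related disease sets that share `overlap_frac` of
#' their genes with the focal set inside common modules and receive
#' `cross_enrichment`-fold extra focal-disease edges there, and size-matched
#' uniform random non-related sets. Fully determined by `spec$seed`; the
#' ambient RNG state is left untouched.
#'
#' @param spec A [synthetic_spec].
#' @return List: `network` (igraph), `bp_sets` (named list of module
#'   [gene_set]s), `focal` ([gene_set]), `diseases` (named list of
#'   [gene_set]s), `labels` (named logical, `TRUE` for planted related sets),
#'   `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  g <- igraph::sample_pa(spec$n_genes, power = 1, m = spec$pa_m,
                         directed = FALSE)
  igraph::V(g)$name <- genes
  extra_from <- character(0); extra_to <- character(0)

  # plant modules: random member subsets + extra internal edges
  members <- vector("list", spec$n_modules)
  for (j in seq_len(spec$n_modules)) {
    size <- sample(spec$module_size[1]:spec$module_size[2], 1)
    mem <- sample(genes, size)
    members[[j]] <- mem
    n_extra <- round(size * spec$module_degree / 2)
    extra_from <- c(extra_from, sample(mem, n_extra, replace = TRUE))
    extra_to <- c(extra_to, sample(mem, n_extra, replace = TRUE))
  }
  names(members) <- sprintf("M%02d", seq_len(spec$n_modules))

  # focal set: a fixed quota from each focal module, remainder random
  focal_mods <- names(members)[seq_len(spec$n_focal_modules)]
  per_mod <- floor(0.8 * spec$focal_size / spec$n_focal_modules)
  focal_genes <- unlist(lapply(members[focal_mods], function(m)
    sample(m, min(per_mod, length(m)))))
  focal_genes <- unique(focal_genes)
  pool <- setdiff(genes, focal_genes)
  focal_genes <- c(focal_genes,
                   sample(pool, max(0, spec$focal_size - length(focal_genes))))

  # related sets: planted signal comes ONLY from the two knobs, so that
  # overlap_frac = 0 with cross_enrichment = 1 reduces them to pure random
  # size-matched draws (the null condition)
  diseases <- list(); labels <- logical(0)
  for (i in seq_len(spec$n_drd)) {
    mods <- sample(focal_mods, spec$modules_per_drd)
    n_overlap <- round(spec$overlap_frac * spec$disease_size)
    per_mod_sh <- n_overlap %/% spec$modules_per_drd
    sh <- unlist(lapply(members[mods], function(m) {
      p <- intersect(focal_genes, m)
      sample(p, min(per_mod_sh, length(p)))
    }))
    sh <- unique(c(sh, sample(intersect(focal_genes,
                                        unique(unlist(members[mods]))),
                              max(0, n_overlap - length(sh)))))
    # with enrichment on, a few disease-only anchor genes per shared module
    # give the extra cross edges endpoints; with enrichment off the whole
    # non-shared part is a uniform draw
    anchors <- if (spec$cross_enrichment > 1)
      unlist(lapply(members[mods], function(m) {
        p <- setdiff(m, c(focal_genes, sh))
        sample(p, min(4, length(p)))
      })) else character(0)
    anchors <- unique(anchors)[seq_len(min(length(unique(anchors)),
                                           spec$disease_size - length(sh)))]
    rest <- sample(setdiff(genes, c(sh, anchors)),
                   max(0, spec$disease_size - length(sh) - length(anchors)))
    dg <- c(sh, anchors, rest)
    id <- sprintf("DRD%02d", i)
    diseases[[id]] <- gene_set(id, dg, type = "disease")
    labels[id] <- TRUE
    # cross-edge enrichment between focal-only and disease-only genes
    # inside the shared modules
    if (spec$cross_enrichment > 1) {
      for (mod in mods) {
        fa <- setdiff(intersect(focal_genes, members[[mod]]), dg)
        da <- setdiff(intersect(dg, members[[mod]]), focal_genes)
        if (length(fa) == 0L || length(da) == 0L) next
        base_edges <- sum(g[fa, da])
        n_new <- round((spec$cross_enrichment - 1) * max(base_edges, 2))
        extra_from <- c(extra_from, sample(fa, n_new, replace = TRUE))
        extra_to <- c(extra_to, sample(da, n_new, replace = TRUE))
      }
    }
  }
  for (i in seq_len(spec$n_nondrd)) {
    id <- sprintf("ND%02d", i)
    diseases[[id]] <- gene_set(id, sample(genes, spec$disease_size),
                               type = "disease")
    labels[id] <- FALSE
  }

  g <- igraph::add_edges(g, rbind(extra_from, extra_to))
  g <- igraph::simplify(g)

  bp_sets <- lapply(names(members), function(id)
    gene_set(id, members[[id]], type = "go_bp"))
  names(bp_sets) <- names(members)

  list(network = g,
       bp_sets = bp_sets,
       focal = gene_set("FOCAL", focal_genes, type = "disease"),
       diseases = diseases,
       labels = labels,
       spec = spec)
}
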
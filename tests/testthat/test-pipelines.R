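test_that("running-sum enrichment score follows the stated increments", {
  ranked <- c("h1", "h2", "m1", "m2")
  expect_equal(gsea_running_score(ranked, c("h1", "h2")), 2)
  expect_equal(gsea_running_score(ranked, c("m1", "m2")), 0)
  # N=6, G=2: hit +2, non-hit -0.5; hits at ranks 2 and 5
  r6 <- c("a", "h1", "b", "c", "h2", "d")
  expect_equal(gsea_running_score(r6, c("h1", "h2")),
               max(cumsum(c(-0.5, 2, -0.5, -0.5, 2, -0.5))))
  # zero-sum KS form
  expect_equal(gsea_running_score(ranked, c("h1", "h2"), form = "ks"), 1)
  # score depends only on the hit/non-hit pattern
  relab <- c("x1", "x2", "y1", "y2")
  expect_equal(gsea_running_score(relab, c("x1", "x2")),
               gsea_running_score(ranked, c("h1", "h2")))
  expect_error(gsea_running_score(ranked, character(0)), "subset")
  expect_error(gsea_running_score(ranked, ranked), "subset")
})

test_that("DINet combines enrichment passes and permutation significance", {
  sim <- tiny_sim()
  emns <- build_emn_catalog(sim$network, sim$bp_sets, fold = 3)
  # identical sets: ES1 = ES2, so es_beta is independent of beta
  csA <- dinet_pair(sim$focal, sim$focal, emns, beta = 0.2, n_perm = 10,
                    seed = 3)
  expect_equal(csA$detail$es1, csA$detail$es2)
  csB <- dinet_pair(sim$focal, sim$focal, emns, beta = 0.8, n_perm = 10,
                    seed = 3)
  expect_equal(csA$detail$es_beta, csB$detail$es_beta)

  # order of eMNs does not change the score
  d1 <- dinet_pair(sim$focal, sim$diseases$DRD01, emns, n_perm = 25, seed = 3)
  d2 <- dinet_pair(sim$focal, sim$diseases$DRD01, rev(emns), n_perm = 25,
                   seed = 3)
  expect_equal(d1$score, d2$score)
  expect_true(d1$score >= 0 && d1$score <= 1)

  # no eligible eMN -> unscorable
  tiny_set <- gene_set("t", emns[[1]]$expanded_genes[1:2])
  expect_true(is.na(dinet_pair(tiny_set, tiny_set, emns, n_perm = 5)$score))
})

test_that("DINet separates a planted pair from a random pair", {
  hits <- 0
  for (seed in 1:5) {
    sim <- tiny_sim(seed = seed + 40)
    emns <- build_emn_catalog(sim$network, sim$bp_sets, fold = 3)
    planted <- dinet_pair(sim$focal, sim$diseases$DRD01, emns,
                          n_perm = 50, seed = 1)$score
    random <- dinet_pair(sim$focal, sim$diseases$ND01, emns,
                         n_perm = 50, seed = 1)$score
    if (is.na(random) || (!is.na(planted) && planted <= random))
      hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("eDMN connectivity averages positive-scoring modules", {
  sim <- tiny_sim()
  emns <- build_emn_catalog(sim$network, sim$bp_sets, fold = 3)
  cs <- diconnectivity_edmn_pair(sim$focal, sim$diseases$DRD01, emns,
                                 fold = 3)
  pos <- cs$detail$weighted_score[cs$detail$weighted_score > 0]
  expect_equal(cs$score, mean(pos))
  expect_equal(cs$n_modules_used, length(pos))

  # fold large enough that both expansions cover a module: every edge is
  # overlap-overlap, so the module contributes 2 * |E|
  m <- emns[[1]]
  A1 <- gene_set("A1", m$base_genes[1:10])
  one <- diconnectivity_edmn_pair(A1, A1, emns[1], fold = 1e6)
  expect_equal(one$detail$weighted_score[1], 2 * igraph::ecount(m$graph))

  # end-to-end equality with a brute-force recomputation over modules
  oracle <- vapply(emns, function(m) {
    if (!eligible_for_pair(m, sim$focal$genes, sim$diseases$DRD01$genes))
      return(NA_real_)
    am <- intersect(sim$focal$genes, m$expanded_genes)
    sm <- intersect(sim$diseases$DRD01$genes, m$expanded_genes)
    ea <- expand_gene_set(m, am, 3)
    es <- expand_gene_set(m, sm, 3)
    unname(classify_oracle(m$graph, ea, es)["score"])
  }, numeric(1))
  oracle <- oracle[!is.na(oracle) & oracle > 0]
  expect_equal(cs$score, mean(oracle))
})

test_that("fold-1 eDMN reduces to eMN connectivity when expansion is identity", {
  # well-separated seeds: fold-1 expansion returns exactly the mapped sets
  g <- igraph::make_graph(c("t1","t2", "t2","t3", "t3","t1",
                            "t1","p1", "p1","p2", "p2","u1",
                            "u1","u2", "u2","u3", "u3","u1"),
                          directed = FALSE)
  mn <- build_mn(g, gene_set("bp", igraph::V(g)$name, type = "go_bp"))
  A <- c("t1", "t2", "t3", "p1", "p2", "u1")  # > 5 mapped
  S <- c("u1", "u2", "u3", "p1", "p2", "t1")
  ea <- expand_gene_set(mn, A, fold = 1)
  es <- expand_gene_set(mn, S, fold = 1)
  if (setequal(ea, A) && setequal(es, S)) {
    edmn <- diconnectivity_edmn_pair(gene_set("A", A), gene_set("S", S),
                                     list(bp = mn), fold = 1)
    emn <- classify_interactions(mn$graph, A, S)$weighted_score
    expect_equal(edmn$score, emn)
  } else skip("fold-1 expansion not identity on this module")
})

test_that("all ten methods score a pair and respect orientation", {
  sim <- tiny_sim()
  emns <- build_emn_catalog(sim$network, sim$bp_sets, fold = 3)
  net <- largest_connected_component(sim$network)
  for (m in diconnect_methods()) {
    cs <- score_pair(m, sim$focal, sim$diseases$DRD01, net, emns,
                     n_perm = 10, seed = 2)
    expect_true(is.finite(cs$score) || is.na(cs$score), info = m)
    expect_identical(cs$method, m)
  }
  # disjoint sets have zero whole-network overlap
  d1 <- gene_set("d1", igraph::V(net)$name[1:10])
  d2 <- gene_set("d2", igraph::V(net)$name[11:20])
  expect_equal(score_pair("DIoverlap-Whole", d1, d2, net)$score, 0)
  # single eligible module: MN mean reduces to that module's statistic
  one <- score_pair("DIconnectivity-MN", sim$focal, sim$diseases$DRD01,
                    net, emns[1])
  if (!is.na(one$score)) expect_equal(one$n_modules_used, 1L)
})

test_that("disease ranking follows each method's orientation", {
  sc <- stats::setNames(c(5, 3, 1, 2, 4, 6, 8, 7, 9, 10), paste0("d", 1:10))
  up <- rank_diseases(sc, "DIconnectivity-eDMN")
  expect_identical(up$disease[1], "d10")
  expect_identical(up$disease, names(sort(sc, decreasing = TRUE)))
  dn <- rank_diseases(sc, "DIcd")
  expect_identical(dn$disease[1], "d3")
  # flags equal hand-computed normal tails
  z <- (sc - mean(sc)) / sd(sc)
  expect_equal(up$significant,
               unname(pnorm(z, lower.tail = FALSE)[up$disease] < 0.05))
  expect_equal(dn$p, unname(pnorm(z[dn$disease])))
  expect_error(rank_diseases(sc, "not-a-method"), "unknown")
})

test_that("relabeling diseases permutes the ranking table identically", {
  sim <- tiny_sim()
  emns <- build_emn_catalog(sim$network, sim$bp_sets, fold = 3)
  sc <- vapply(sim$diseases, function(S)
    diconnectivity_edmn_pair(sim$focal, S, emns, fold = 3)$score, numeric(1))
  t1 <- rank_diseases(sc, "DIconnectivity-eDMN")
  names(sc) <- paste0("renamed_", names(sc))
  t2 <- rank_diseases(sc, "DIconnectivity-eDMN")
  expect_identical(paste0("renamed_", t1$disease), t2$disease)
  expect_equal(t1$score, t2$score)
})

test_that("fold sweep reports AUC per fold deterministically", {
  sim <- tiny_sim()
  emns <- build_emn_catalog(sim$network, sim$bp_sets, fold = 3)
  one <- sweep_fold(sim$focal, sim$diseases, emns, sim$labels, folds = 2)
  expect_identical(nrow(one), 1L)
  tab1 <- sweep_fold(sim$focal, sim$diseases, emns, sim$labels, folds = 1:3)
  tab2 <- sweep_fold(sim$focal, sim$diseases, emns, sim$labels, folds = 1:3)
  expect_identical(tab1, tab2)
  expect_true(all(tab1$auc >= 0 & tab1$auc <= 1))
  expect_true(attr(tab1, "best_fold") %in% 1:3)
})
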
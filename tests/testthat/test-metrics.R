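test_that("closest distance reproduces the worked example and the oracle", {
  ex <- fig1_example()
  expect_equal(closest_distance_AS(ex$g, ex$A, ex$S), 4 / 7)
  expect_equal(closest_distance_AS(ex$g, ex$A, ex$A), 0)

  g <- largest_connected_component(random_named_graph(12, 0.3, seed = 4))
  nodes <- igraph::V(g)$name
  A <- nodes[1:5]; S <- nodes[4:8]
  D <- fw_distances(g)
  expect_equal(closest_distance_AS(g, A, S),
               mean(apply(D[A, S, drop = FALSE], 1, min)))
})

test_that("closest distance S->A is the set-swapped counterpart", {
  ex <- fig1_example()
  # per-s minima to A: s1 -> 1 (a1), s2 -> 1 (a3), overlap genes -> 0
  expect_equal(closest_distance_SA(ex$g, ex$S, ex$A), 2 / 6)
  expect_equal(closest_distance_SA(ex$g, ex$A, ex$A), 0)
  g <- largest_connected_component(random_named_graph(12, 0.3, seed = 13))
  nodes <- igraph::V(g)$name
  A <- nodes[1:4]; S <- nodes[6:11]
  D <- fw_distances(g)
  expect_equal(closest_distance_SA(g, S, A),
               mean(apply(D[S, A, drop = FALSE], 1, min)))
})

test_that("mean pairwise distance matches the all-pairs oracle", {
  path <- igraph::make_graph(c("a","m", "m","x", "x","s"), directed = FALSE)
  expect_equal(shortest_distance(path, "a", "s"), 3)
  expect_equal(shortest_distance(path, "a", "a"), 0)
  g <- largest_connected_component(random_named_graph(12, 0.3, seed = 21))
  nodes <- igraph::V(g)$name
  A <- nodes[1:5]; S <- nodes[5:9]
  expect_equal(shortest_distance(g, A, S), mean(fw_distances(g)[A, S]))
})

test_that("distance means exclude (or impute) unreachable contributions", {
  g <- igraph::make_graph(c("a1","s1", "a2","b2"), directed = FALSE)
  expect_warning(v <- closest_distance_AS(g, c("a1", "a2"), "s1"),
                 "unreachable")
  expect_equal(v, 1)  # a2 excluded
  expect_warning(v2 <- closest_distance_AS(g, c("a1", "a2"), "s1",
                                           impute_unreachable = TRUE),
                 "imputed")
  expect_equal(v2, (1 + igraph::diameter(g) + 1) / 2)
  expect_error(suppressWarnings(closest_distance_AS(g, "a2", "s1")),
               "unreachable")
})

test_that("Jaccard coefficient basics", {
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(sprintf("x%d", 1:10), sprintf("x%d", 6:20)), 5 / 20)
  expect_equal(jaccard(c("A"), c("A", "B")), jaccard(c("A", "B"), c("A")))
  expect_error(jaccard(character(0), character(0)), "empty")
})

test_that("interaction classification matches definitions and the oracle", {
  g1 <- igraph::make_graph(c("a","s"), directed = FALSE)
  ic1 <- classify_interactions(g1, "a", "s")
  expect_equal(ic1$h1, 1)
  expect_equal(ic1$weighted_score, 1)

  g2 <- igraph::make_graph(c("o1","o2"), directed = FALSE)
  ic2 <- classify_interactions(g2, c("o1", "o2"), c("o1", "o2"))
  expect_equal(ic2$h4, 1)
  expect_equal(ic2$weighted_score, 2)

  g3 <- igraph::make_graph(c("a1","a2", "s1","s2"), directed = FALSE)
  ic3 <- classify_interactions(g3, c("a1", "a2"), c("s1", "s2"))
  expect_equal(ic3$weighted_score, 0)

  ex <- fig1_example()
  ic <- classify_interactions(ex$g, ex$A, ex$S)
  oc <- classify_oracle(ex$g, ex$A, ex$S)
  expect_equal(c(ic$h1, ic$h2, ic$h3, ic$h4), unname(oc[1:4]))

  for (seed in 1:5) {
    g <- random_named_graph(20, 0.2, seed = seed)
    nodes <- igraph::V(g)$name
    set.seed(seed + 100)
    A <- sample(nodes, 8); S <- sample(nodes, 8)
    ic <- classify_interactions(g, A, S)
    oc <- classify_oracle(g, A, S)
    expect_equal(c(ic$h1, ic$h2, ic$h3, ic$h4, ic$weighted_score),
                 unname(oc))
  }
})

test_that("classification symmetry: swapping sets exchanges h2 and h3", {
  g <- random_named_graph(25, 0.2, seed = 31)
  nodes <- igraph::V(g)$name
  A <- nodes[1:10]; S <- nodes[6:15]
  ab <- classify_interactions(g, A, S)
  ba <- classify_interactions(g, S, A)
  expect_equal(ab$h1, ba$h1)
  expect_equal(ab$h2, ba$h3)
  expect_equal(ab$h3, ba$h2)
  expect_equal(ab$h4, ba$h4)
  expect_equal(ab$weighted_score, ba$weighted_score)
})

test_that("connectivity monotonicity under edge deletion and overlap growth", {
  g <- random_named_graph(20, 0.25, seed = 17)
  nodes <- igraph::V(g)$name
  A <- nodes[1:8]; S <- nodes[5:12]
  base <- classify_interactions(g, A, S)$weighted_score
  el <- igraph::as_edgelist(g)
  for (i in sample(nrow(el), 5)) {
    g2 <- igraph::delete_edges(g, paste(el[i, 1], el[i, 2], sep = "|"))
    expect_lte(classify_interactions(g2, A, S)$weighted_score, base)
  }
  # adding an overlap gene (fixed edges) never decreases the score
  extra <- setdiff(nodes, union(A, S))[1]
  expect_gte(classify_interactions(g, c(A, extra), c(S, extra))$weighted_score,
             base)
})

test_that("closest distance is asymmetric but bounded by the pairwise mean", {
  ex <- fig1_example()
  expect_false(isTRUE(all.equal(
    closest_distance_AS(ex$g, ex$A, ex$S),
    closest_distance_AS(ex$g, ex$S, ex$A))))
  for (seed in 1:4) {
    g2 <- largest_connected_component(random_named_graph(15, 0.25, seed = seed))
    nodes <- igraph::V(g2)$name
    A <- nodes[1:5]; S <- nodes[6:10]
    expect_lte(closest_distance_AS(g2, A, S), shortest_distance(g2, A, S))
  }
})

test_that("gene-set expansion inside a module honors the size contract", {
  sim <- tiny_sim()
  emns <- build_emn_catalog(sim$network, sim$bp_sets, fold = 3)
  m <- emns[[1]]
  mapped <- m$expanded_genes[1:7]
  expect_length(expand_gene_set(m, mapped, fold = 3), 21)
  expect_setequal(expand_gene_set(m, mapped, fold = 1e6),
                  m$expanded_genes)
  expect_error(expand_gene_set(m, character(0)), "empty")
  expect_error(expand_gene_set(m, "not_a_gene"), "inside")
})

test_that("fold-1 expansion of well-separated seeds returns the seeds", {
  # two triangles joined by one long path: seeds = one triangle
  g <- igraph::make_graph(c("t1","t2", "t2","t3", "t3","t1",
                            "t1","p1", "p1","p2", "p2","p3", "p3","u1",
                            "u1","u2", "u2","u3", "u3","u1"),
                          directed = FALSE)
  mn <- build_mn(g, gene_set("bp", igraph::V(g)$name, type = "go_bp"))
  seeds <- c("t1", "t2", "t3")
  got <- expand_gene_set(mn, seeds, fold = 1)
  # oracle: seeds dominate the linear-solve ranking at restart 0.5
  p <- rwr_solve(g, seeds, 0.5)
  expect_setequal(got, names(sort(p, decreasing = TRUE))[1:3])
  expect_setequal(got, seeds)
})

test_that("participation proportions count incidence to scored edges", {
  g0 <- igraph::make_graph(c("a1","a2", "s1","s2"), directed = FALSE)
  expect_equal(unname(gene_participation(g0, c("a1","a2"), c("s1","s2"))),
               c(0, 0))
  kb <- igraph::make_full_bipartite_graph(3, 3)
  igraph::V(kb)$name <- c("a1","a2","a3","s1","s2","s3")
  expect_equal(unname(gene_participation(kb, c("a1","a2","a3"),
                                         c("s1","s2","s3"))), c(1, 1))
  g <- random_named_graph(18, 0.2, seed = 23)
  nodes <- igraph::V(g)$name
  A <- nodes[1:7]; S <- nodes[5:11]
  got <- gene_participation(g, A, S)
  # brute-force incidence scan
  el <- igraph::as_edgelist(g)
  lab <- function(x) (x %in% A) + 2 * (x %in% S)  # 1=a,2=s,3=o
  counted <- apply(el, 1, function(e) {
    l <- sort(lab(e))
    identical(l, c(1, 2)) || (l[2] == 3 && l[1] >= 1)
  })
  inc <- unique(c(el[counted, 1], el[counted, 2]))
  expect_equal(unname(got), c(mean(A %in% inc), mean(S %in% inc)))
})
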
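# Independent oracles used to freeze expected values: these deliberately
# avoid the package's code paths (brute force, dense linear algebra,
# exhaustive enumeration).

# all-pairs hop counts by Floyd-Warshall on a dense matrix
fw_distances <- function(net) {
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  el <- igraph::as_edgelist(net)
  for (i in seq_len(nrow(el))) {
    D[el[i, 1], el[i, 2]] <- 1
    D[el[i, 2], el[i, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# RWR fixed point by direct dense linear solve: p = r (I - (1-r) W)^-1 p0
rwr_solve <- function(net, seeds, r) {
  nodes <- igraph::V(net)$name
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  deg <- colSums(A)
  W <- sweep(A, 2, ifelse(deg > 0, deg, 1), "/")
  W[, deg == 0] <- 0
  p0 <- as.numeric(nodes %in% seeds) / sum(nodes %in% seeds)
  p <- r * solve(diag(length(nodes)) - (1 - r) * W, p0)
  names(p) <- nodes
  p
}

# exhaustive edge-scan classification with explicit if/else per edge
classify_oracle <- function(g, A, S) {
  a <- intersect(A, igraph::V(g)$name)
  s <- intersect(S, igraph::V(g)$name)
  el <- igraph::as_edgelist(g)
  h <- c(h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (i in seq_len(nrow(el))) {
    u <- el[i, 1]; v <- el[i, 2]
    lab <- function(x) {
      if (x %in% a && x %in% s) "o" else if (x %in% a) "a"
      else if (x %in% s) "s" else "n"
    }
    lu <- lab(u); lv <- lab(v)
    key <- paste(sort(c(lu, lv)), collapse = "")
    if (key == "as") h["h1"] <- h["h1"] + 1
    else if (key == "os") h["h2"] <- h["h2"] + 1
    else if (key == "ao") h["h3"] <- h["h3"] + 1
    else if (key == "oo") h["h4"] <- h["h4"] + 1
  }
  c(h, score = unname(h["h1"] + h["h2"] + h["h3"] + 2 * h["h4"]))
}

# AUC by exhaustive positive x negative pair counting, ties = 1/2
auc_oracle <- function(scores, labels, smaller_better = FALSE) {
  s <- if (smaller_better) -scores else scores
  pos <- s[labels]; neg <- s[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# named Erdos-Renyi graph
random_named_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

# the worked 10-node example graph: seven focal genes a1..a7, disease genes
# s1, s2 plus the four overlap genes a4..a7, and a bridge node x
fig1_example <- function() {
  edges <- c("a1", "s1", "a2", "x", "x", "s1", "a3", "s2", "s1", "s2",
             "a4", "s1", "a5", "s1", "a6", "s2", "a7", "s2")
  g <- igraph::make_graph(edges, directed = FALSE)
  list(g = g,
       A = paste0("a", 1:7),
       S = c("s1", "s2", "a4", "a5", "a6", "a7"))
}

# small planted instance shared by several tests
tiny_sim <- function(seed = 7, ...) {
  generate_synthetic(synthetic_spec(
    n_genes = 600, n_modules = 6, module_size = c(30, 40), n_focal_modules = 3,
    focal_size = 70, disease_size = 60, n_drd = 2, n_nondrd = 4,
    modules_per_drd = 2, seed = seed, ...))
}
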
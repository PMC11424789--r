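test_that("proportional thresholding keeps the strongest symmetrized edges", {
  set.seed(41)
  w <- matrix(runif(9), 3); diag(w) <- 0
  g1 <- threshold_network(w, density = 1)
  expect_equal(g1$adjacency, matrix(1, 3, 3) - diag(3))
  # density for exactly one edge: the largest max(w_ij, w_ji) survives
  gsmall <- threshold_network(w, density = 1 / 3)
  ws <- pmax(w, t(w)); diag(ws) <- 0
  top <- which(ws == max(ws), arr.ind = TRUE)[1, ]
  expect_equal(sum(gsmall$adjacency) / 2, 1)
  expect_equal(gsmall$adjacency[top[1], top[2]], 1L)
})

test_that("threshold edge sets are nested in density", {
  set.seed(42)
  w <- matrix(runif(144), 12); diag(w) <- 0
  e1 <- threshold_network(w, 0.1)$adjacency
  e2 <- threshold_network(w, 0.3)$adjacency
  expect_true(all(e2[e1 == 1] == 1))
  expect_error(threshold_network(w, 1e-6), "zero edges")
})

test_that("complete and star graphs give the textbook metric values", {
  k4 <- matrix(1, 4, 4) - diag(4)
  m <- node_metrics(k4)
  expect_equal(m$degree, rep(3L, 4))
  expect_equal(m$cost, rep(1, 4))
  expect_equal(m$clustering, rep(1, 4))
  expect_equal(m$local_efficiency, rep(1, 4))
  expect_equal(m$betweenness, rep(0, 4))
  expect_equal(m$avg_path_length, rep(1, 4))
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  s <- node_metrics(star)
  expect_equal(s$betweenness[1], 1)
  expect_equal(s$clustering[2:4], rep(0, 3))
  expect_equal(s$avg_path_length[1], 1)
  expect_equal(s$avg_path_length[2:4], rep(5 / 3, 3))
})

test_that("metrics equal brute force on exhaustive small graphs", {
  for (n in 2:4) {
    for (bits in 0:(2^(n * (n - 1) / 2) - 1)) {
      adj <- adj_from_bits(n, bits)
      got <- node_metrics(adj)
      want <- brute_node_metrics(adj)
      for (col in names(want))
        expect_equal(got[[col]], want[[col]], tolerance = 1e-10,
                     label = sprintf("n=%d bits=%d col=%s", n, bits, col))
    }
  }
  # 5-node graphs: a deterministic systematic subsample of all 1024
  for (bits in seq(0, 1023, by = 7)) {
    adj <- adj_from_bits(5, bits)
    got <- node_metrics(adj)
    want <- brute_node_metrics(adj)
    for (col in names(want))
      expect_equal(got[[col]], want[[col]], tolerance = 1e-10,
                   label = sprintf("n=5 bits=%d col=%s", bits, col))
  }
})

test_that("metrics agree with igraph on random 12-node graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:30) {
    set.seed(seed)
    w <- matrix(runif(144), 12)
    adj <- threshold_network(w, density = 0.2)$adjacency
    got <- node_metrics(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(got$degree, unname(igraph::degree(g)))
    expect_equal(got$betweenness,
                 unname(igraph::betweenness(g)) / (11 * 10 / 2),
                 tolerance = 1e-10)
    expect_equal(got$clustering,
                 igraph::transitivity(g, type = "localundirected",
                                      isolates = "zero"),
                 tolerance = 1e-10)
    # Latora-Marchiori on the neighbor-induced subgraph, using igraph's
    # independent shortest-path machinery
    le_oracle <- vapply(seq_len(12), function(v) {
      nb <- as.integer(igraph::neighbors(g, v))
      if (length(nb) < 2) return(0)
      sub <- igraph::induced_subgraph(g, nb)
      Ds <- igraph::distances(sub)
      mean(1 / Ds[upper.tri(Ds)])
    }, 0)
    expect_equal(got$local_efficiency, le_oracle, tolerance = 1e-10)
    D <- igraph::distances(g)
    diag(D) <- Inf
    apl <- apply(D, 1, function(v) {
      f <- is.finite(v); if (!any(f)) NA_real_ else mean(v[f])
    })
    expect_equal(got$avg_path_length, unname(apl), tolerance = 1e-10)
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(43)
  w <- matrix(runif(64), 8)
  adj <- threshold_network(w, 0.3)$adjacency
  perm <- sample(8)
  m1 <- node_metrics(adj)
  m2 <- node_metrics(adj[perm, perm])
  for (col in c("degree", "cost", "clustering", "local_efficiency",
                "betweenness", "avg_path_length"))
    expect_equal(m2[[col]], m1[[col]][perm], tolerance = 1e-10)
  # cost identity holds for every output
  expect_equal(m1$cost, m1$degree / 7, tolerance = 1e-12)
})

test_that("SOZ feature extraction selects the requested node", {
  set.seed(44)
  conn <- list(delta = matrix(runif(36), 6), theta = matrix(runif(36), 6),
               alpha = matrix(runif(36), 6), beta = matrix(runif(36), 6))
  fl <- inflow_outflow(conn)
  colnames(fl$inflow) <- colnames(fl$outflow) <- names(conn)
  mets <- lapply(conn, function(m) node_metrics(threshold_network(m, 0.4)))
  f2 <- extract_soz_features(fl, mets, 2, "P1", "seizure_free")
  f5 <- extract_soz_features(fl, mets, 5, "P1", "seizure_free")
  expect_equal(nrow(f2), 32)
  expect_equal(f2$value[f2$band == "delta" & f2$measure == "inflow"],
               unname(fl$inflow[2, "delta"]))
  expect_equal(f5$value[f5$band == "beta" & f5$measure == "degree"],
               as.numeric(mets$beta$degree[5]))
  expect_error(extract_soz_features(fl, mets[1:3], 2, "P1", "g"), "missing")
})
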
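test_that("connection weights follow the volume-sum convention", {
  counts <- matrix(c(0, 10, 10, 0), 2, 2)
  fc <- fiber_connectivity(counts, volumes = c(2, 3), region_names = c("a", "b"))
  net <- build_weighted_network(fc)
  expect_equal(net$weights["a", "b"], 2.0)  # 10 / (2 + 3)
  expect_equal(net$weights["b", "a"], 2.0)
  # zero count -> zero weight; alternative conventions
  expect_equal(build_weighted_network(fiber_connectivity(matrix(0, 2, 2), c(2, 3), c("a", "b")))$weights["a", "b"], 0)
  expect_equal(build_weighted_network(fc, "product")$weights["a", "b"], 10 / 6)
  expect_equal(build_weighted_network(fc, "mean")$weights["a", "b"], 4.0)
})

test_that("invalid fiber inputs are rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)          # asymmetric
  expect_error(fiber_connectivity(m, c(1, 1), c("a", "b")), "symmetric")
  m2 <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(fiber_connectivity(m2, c(1, 1), c("a", "b")), "nonnegative")
  m3 <- matrix(c(1, 2, 2, 0), 2, 2)
  expect_error(fiber_connectivity(m3, c(1, 1), c("a", "b")), "diagonal")
  expect_error(fiber_connectivity(matrix(0, 2, 2), c(1, -1), c("a", "b")), "positive")
})

test_that("node strength sums incident weights", {
  # 4-region star: center a connected to b, c, d with unit weights
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- w[2:4, 1] <- 1
  star <- weighted_network(w, letters[1:4])
  s <- node_strength(star)
  expect_equal(s$value, c(3, 1, 1, 1))
  # random network equals the row-sum oracle
  net <- withr::with_seed(5, random_network(6))
  expect_equal(node_strength(net)$value, unname(rowSums(net$weights)))
  # isolated region has strength 0
  w0 <- matrix(0, 3, 3); w0[1, 2] <- w0[2, 1] <- 1
  expect_equal(node_strength(weighted_network(w0, letters[1:3]))$value[3], 0)
})

test_that("betweenness matches hand-enumerated paths on canonical graphs", {
  # path a-b-c: b lies on the single a..c shortest path -> normalized 1
  pn <- path_network(c(1, 1))
  bw <- betweenness_centrality(pn)
  expect_equal(bw$value, c(0, 1, 0))
  # complete graph: no interior nodes on any shortest path
  expect_equal(betweenness_centrality(complete_network(5))$value, rep(0, 5))
  expect_error(betweenness_centrality(weighted_network(matrix(0, 2, 2), c("a", "b"))),
               "at least 3")
})

test_that("average path length matches hand enumeration and flags isolation", {
  pn <- path_network(c(1, 1))
  apl <- average_path_length(pn)
  expect_equal(apl$value, c(1.5, 1, 1.5))
  expect_equal(average_path_length(complete_network(4))$value, rep(1, 4))
  # region with no reachable partner -> NA, not zero
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 2
  apl2 <- average_path_length(weighted_network(w, letters[1:3]))
  expect_equal(apl2$value[1:2], c(0.5, 0.5))
  expect_true(is.na(apl2$value[3]))
})

test_that("betweenness and path length equal the exhaustive-enumeration oracle", {
  withr::with_seed(42, {
    for (i in 1:100) {
      n <- sample(4:7, 1)
      net <- random_network(n, density = runif(1, 0.4, 0.9), dyadic = i %% 2 == 0)
      oracle <- oracle_path_metrics(net)
      expect_equal(betweenness_centrality(net)$value, oracle$betweenness,
                   tolerance = 1e-9)
      got <- average_path_length(net)$value
      expect_equal(is.na(got), is.na(oracle$apl))
      expect_equal(got[!is.na(got)], oracle$apl[!is.na(oracle$apl)],
                   tolerance = 1e-9)
    }
  })
})

test_that("eigenvector centrality matches a dense eigen-decomposition", {
  # complete graph with equal weights: uniform 1/sqrt(R)
  ec <- eigenvector_centrality(complete_network(6))
  expect_equal(ec$value, rep(1 / sqrt(6), 6), tolerance = 1e-9)
  # random connected networks vs base eigen() as oracle
  withr::with_seed(9, {
    for (i in 1:20) {
      net <- random_network(5, density = 0.9)
      if (igraph::components(igraph::graph_from_adjacency_matrix(
        net$weights > 0, mode = "undirected"))$no > 1) next
      ev <- eigen(net$weights, symmetric = TRUE)
      ref <- ev$vectors[, which.max(ev$values)]
      if (sum(ref) < 0) ref <- -ref
      expect_equal(eigenvector_centrality(net)$value, ref, tolerance = 1e-8)
      # scale invariance
      scaled <- weighted_network(net$weights * 10, net$region_names)
      expect_equal(eigenvector_centrality(scaled)$value,
                   eigenvector_centrality(net)$value, tolerance = 1e-8)
    }
  })
  # disconnected input refused, naming components
  w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 1
  expect_error(eigenvector_centrality(weighted_network(w, letters[1:4])),
               "2 components")
})

test_that("region relabeling permutes every metric identically", {
  net <- withr::with_seed(13, random_network(7, density = 0.8))
  perm <- withr::with_seed(14, sample(7))
  pnet <- weighted_network(net$weights[perm, perm], net$region_names[perm])
  for (metric in list(node_strength, betweenness_centrality, average_path_length)) {
    expect_equal(metric(pnet)$value, metric(net)$value[perm], tolerance = 1e-10)
  }
})

test_that("weight scaling acts as expected on each metric", {
  net <- withr::with_seed(21, random_network(6, density = 0.9))
  scaled <- weighted_network(net$weights * 3, net$region_names)
  expect_equal(betweenness_centrality(scaled)$value,
               betweenness_centrality(net)$value, tolerance = 1e-10)
  expect_equal(average_path_length(scaled)$value,
               average_path_length(net)$value / 3, tolerance = 1e-10)
  expect_equal(node_strength(scaled)$value, node_strength(net)$value * 3)
})

test_that("flatten_metrics builds <MetricTag>__<region> columns sorted by metric then region", {
  spec <- cohort_spec(n_obese = 3, n_overweight = 3, n_regions = 10,
                      n_metabolites = 2, informative_regions = 1,
                      informative_metabolites = 1, seed = 4)
  co <- generate_cohort(spec, blocks = "brain")
  ft <- connectome_features(co$fibers,
                            metrics = c("NodeBWCent", "AvPathLength", "Strength", "EigCent"))
  expect_equal(ncol(ft) - 1L, 40)  # 4 metrics x 10 regions
  cols <- setdiff(names(ft), "subject_id")
  expect_identical(cols, sort(cols))
  expect_true(all(grepl("^(NodeBWCent|AvPathLength|Strength|EigCent)__roi_\\d{3}$", cols)))
  # default selection: two metrics per region
  ft2 <- connectome_features(co$fibers)
  expect_equal(ncol(ft2) - 1L, 20)
  # mismatched region sets across subjects error out
  tabs <- lapply(co$fibers[1:2], function(fc)
    node_metric_table(build_weighted_network(fc), "NodeBWCent"))
  tabs[[2]] <- tabs[[2]][c(2:10, 1), ]
  expect_error(flatten_metrics(tabs, "NodeBWCent"), "region set")
})
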
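test_that("hub scores match eigen and igraph oracles and scale invariance", {
  # weighted triangle with weights 3, 2, 1
  adj <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  adj["a", "b"] <- adj["b", "a"] <- 3
  adj["a", "c"] <- adj["c", "a"] <- 2
  adj["b", "c"] <- adj["c", "b"] <- 1
  net <- structure(list(markers = rownames(adj), adjacency = adj,
                        r = adj / 3), class = "group_network")
  m <- node_metrics(net, degree_threshold = 0)
  expect_equal(m$hubscore, unname(hubscore_oracle(adj)), tolerance = 1e-8)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            weighted = TRUE)
  expect_equal(m$hubscore, unname(igraph::hits_scores(ig)$hub),
               tolerance = 1e-6)
  # uniform scaling of weights leaves the hub score unchanged
  net2 <- net; net2$adjacency <- adj * 13.7
  expect_equal(node_metrics(net2, 0)$hubscore, m$hubscore,
               tolerance = 1e-9)
  expect_equal(m$strength, unname(rowSums(adj)))
})

test_that("hub scores respect star symmetry, isolation and the zero graph", {
  n <- 6
  adj <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  adj[1, 2:5] <- adj[2:5, 1] <- 1      # star centered on v1; v6 isolated
  net <- structure(list(markers = rownames(adj), adjacency = adj,
                        r = adj), class = "group_network")
  m <- node_metrics(net, degree_threshold = 0.5)
  expect_equal(m$hubscore[1], 1)
  expect_true(all(m$hubscore[2:5] < 1))
  expect_equal(sd(m$hubscore[2:5]), 0)           # leaves identical
  expect_equal(m$hubscore[6], 0)                 # isolated node
  expect_equal(m$degree[6], 0)
  expect_equal(m$strength[6], 0)
  expect_equal(m$degree[1], 4)

  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  netz <- structure(list(markers = letters[1:3], adjacency = zero,
                         r = zero), class = "group_network")
  expect_message(mz <- node_metrics(netz), "all-zero")
  expect_equal(mz$hubscore, rep(0, 3))
})

test_that("hub and authority coincide on symmetric graphs (HITS oracle)", {
  set.seed(44)
  for (i in 1:25) {
    adj <- random_adjacency(sample(4:9, 1))
    # independent HITS double iteration: h <- A a; a <- A h
    h <- rep(1, nrow(adj))
    for (k in 1:2000) {
      a <- adj %*% h; a <- a / sqrt(sum(a^2))
      h <- adj %*% a; h <- h / sqrt(sum(h^2))
    }
    h <- as.vector(h / max(h))
    net <- structure(list(markers = rownames(adj), adjacency = adj,
                          r = adj), class = "group_network")
    expect_equal(node_metrics(net, 0)$hubscore, h, tolerance = 1e-8)
  }
})

test_that("degree uses the edge-inclusion threshold on |r|", {
  co <- simulate_cohort(sim_config(seed = 41, missing_rate = 0))
  net <- build_group_network(co$expression, "CRS0", "M")
  m <- node_metrics(net, degree_threshold = 0.3)
  expect_true(all(m$degree <= 10))
  expect_equal(m$degree,
               as.integer(rowSums(net$adjacency >= 0.3)))
  expect_true(any(m$degree < 10))    # not trivially n - 1
  expect_equal(max(m$hubscore), 1)
})

test_that("Stouffer combination matches normal-quantile closed forms", {
  s <- stouffer_meta(0.2, 1)
  expect_equal(s$p, 0.2)                      # k = 1 identity
  expect_equal(s$direction, 1)
  expect_equal(stouffer_meta(0.2, -1)$direction, -1)
  s2 <- stouffer_meta(c(0.1, 0.1), c(1, 1))
  expect_equal(s2$z, 2 * qnorm(0.95) / sqrt(2))
  expect_equal(s2$z, 2.326, tolerance = 1e-3)
  expect_equal(s2$p, 0.020, tolerance = 1e-3)
  # equal and opposite effects cancel exactly
  s3 <- stouffer_meta(c(0.03, 0.03), c(1, -1))
  expect_equal(s3$p, 1)
  expect_equal(s3$direction, 0)
  expect_equal(stouffer_meta(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_error(stouffer_meta(numeric(0), numeric(0)), "empty")
  expect_error(stouffer_meta(c(0.1, 0.2), 1), "one direction")
  expect_warning(stouffer_meta(c(0, 0.5), c(1, 1)), "clamped")
  # monotone: decreasing a concordant p never increases the combined p
  set.seed(50)
  for (i in 1:50) {
    p <- runif(3); d <- c(1, 1, 1)
    j <- sample(3, 1); p2 <- p; p2[j] <- p[j] / 3
    expect_lte(stouffer_meta(p2, d)$p, stouffer_meta(p, d)$p + 1e-12)
  }
})

test_that("hub-change self-comparison is null and the test is reproducible", {
  co <- simulate_cohort(sim_config(seed = 43, missing_rate = 0))
  ht <- hub_change_test(co$expression, "CRS0", sex = "M",
                        reference_group = "CRS0", n_perm = 200, seed = 6)
  expect_equal(ht$metrics$observed_diff, rep(0, 11))
  expect_equal(ht$metrics$p, rep(1, 11))
  ht1 <- hub_change_test(co$expression, "CRS35", sex = "M",
                         n_perm = 200, seed = 7)
  ht2 <- hub_change_test(co$expression, "CRS35", sex = "M",
                         n_perm = 200, seed = 7)
  expect_identical(ht1$metrics, ht2$metrics)
  expect_true(all(ht1$metrics$p >= 1 / 201 - 1e-15))
})

test_that("compartment trajectories average the right markers and meta-combine", {
  co <- simulate_cohort(sim_config(seed = 47, missing_rate = 0))
  tests <- list(
    CRS21 = hub_change_test(co$expression, "CRS21", sex = "F",
                            n_perm = 150, seed = 8),
    CRS35 = hub_change_test(co$expression, "CRS35", sex = "F",
                            n_perm = 150, seed = 9))
  traj <- compartment_trajectory(tests)
  expect_equal(nrow(traj), 6)      # 2 groups x 3 compartments
  astro <- traj[traj$group == "CRS35" &
                  traj$compartment == "astroglial", ]
  met <- tests$CRS35$metrics
  mk <- c("GLT1", "GFAP", "GS")
  expect_equal(astro$mean_hubscore,
               mean(met$hubscore[met$marker %in% mk]))
  st <- stouffer_meta(met$p[met$marker %in% mk],
                      sign(met$observed_diff[met$marker %in% mk]),
                      zero_sub = 1 / 151)
  expect_equal(astro$meta_p, st$p)
  # single-marker compartment: meta p equals the marker p
  pan1 <- marker_panel(c("GLT1", "GAD67"), c("astroglial", "GABAergic"),
                       c("protein", "protein"))
  t1 <- compartment_trajectory(tests["CRS35"], pan1)
  expect_equal(t1$meta_p[t1$compartment == "astroglial"],
               met$p[met$marker == "GLT1"])
  # all-p-1 boundary gives meta p 1
  fake <- tests["CRS35"]
  fake$CRS35$metrics$p <- rep(1, 11)
  expect_equal(unique(compartment_trajectory(fake)$meta_p), 1)
})
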
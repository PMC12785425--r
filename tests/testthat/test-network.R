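test_that("group networks carry consistent r, Fisher z and adjacency", {
  co <- simulate_cohort(sim_config(seed = 5, missing_rate = 0))
  net <- build_group_network(co$expression, "CRS0", "M")
  expect_s3_class(net, "group_network")
  expect_equal(net$n_samples, 8)
  expect_equal(net$r, t(net$r))
  expect_equal(unname(diag(net$r)), rep(1, 11))
  off <- upper.tri(net$r)
  expect_true(all(abs(net$r[off]) <= 1))
  expect_equal(net$z[off], atanh(net$r[off]))
  expect_equal(net$adjacency[off], abs(net$r[off]))
  expect_equal(unname(diag(net$adjacency)), rep(0, 11))
  # atanh oracle values
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(atanh(0), 0)
})

test_that("degenerate cells are rejected and perfect correlation clamped", {
  co <- suppressWarnings(simulate_cohort(
    sim_config(n_per_cell = 3, seed = 5, missing_rate = 0)))
  expect_error(build_group_network(co$expression, "CRS0", "M"), "minimum")
  tab <- data.frame(animal_id = as.character(1:5), sex = "M",
                    group = "CRS0", A = 1:5, B = rep(2, 5), C = 6:10)
  expect_error(build_group_network(tab, "CRS0", "M"), "constant marker.*B")
  tab$B <- 2 * (1:5)
  expect_message(net <- build_group_network(tab, "CRS0", "M"), "clamped")
  expect_true(all(is.finite(net$z[upper.tri(net$z)])))
})

test_that("module detection respects min size, labels and planted structure", {
  pan <- default_panel()
  # exactly uncorrelated markers: no module forms, all 11 unassigned
  mk_net <- function(r) {
    structure(list(r = r, markers = rownames(r)), class = "group_network")
  }
  r0 <- diag(11); dimnames(r0) <- list(pan$marker, pan$marker)
  p0 <- detect_modules(mk_net(r0))
  expect_equal(max(p0), 0)
  expect_true(all(p0 == 0))
  # planted 4/4/3 blocks are recovered exactly, labels in marker order
  part <- setNames(rep(1:3, c(4, 4, 3)), pan$marker)
  tab <- planted_module_dataset(part, 0.8, 0, n = 200, seed = 2)
  pm <- detect_modules(build_group_network(tab, "CRS0", "M"))
  expect_equal(as.integer(pm), as.integer(part))
  # a tight 2-marker cluster isolated from the rest stays unassigned
  r2 <- diag(11) * 0.0; r2[] <- 0
  r2[1, 2] <- r2[2, 1] <- 0.95
  diag(r2) <- 1
  dimnames(r2) <- list(pan$marker, pan$marker)
  p2 <- detect_modules(mk_net(r2))
  expect_equal(unname(p2[1:2]), c(0L, 0L))
  expect_equal(max(p2), 0)
  # no module can ever be smaller than min_size
  for (s in 1:20) {
    set.seed(s)
    rr <- cor(matrix(rnorm(8 * 11), 8))
    dimnames(rr) <- list(pan$marker, pan$marker)
    ps <- detect_modules(mk_net(rr))
    if (max(ps) > 0)
      expect_true(all(table(ps[ps > 0]) >= 3))
    expect_identical(ps, detect_modules(mk_net(rr)))  # deterministic
  }
})

test_that("module preservation is the best-overlap proportion", {
  mk <- function(x) {
    names(x) <- paste0("g", seq_along(x))
    structure(as.integer(x), names = names(x), class = "module_partition")
  }
  a <- mk(c(1, 1, 1, 2, 2, 2))
  b <- mk(c(1, 1, 2, 1, 2, 2))          # A {1,2,3} vs B {1,2,4}; {3,5,6}
  expect_equal(unname(module_preservation(a, b)), c(2 / 3, 2 / 3))
  expect_equal(unname(module_preservation(a, a)), c(1, 1))
  expect_equal(unname(module_preservation(a, mk(rep(0, 6)))), c(0, 0))
  expect_message(out <- module_preservation(mk(rep(0, 6)), a),
                 "no modules")
  expect_length(out, 0)
})

test_that("preservation matches exhaustive enumeration on random partitions", {
  set.seed(30)
  markers <- paste0("m", 1:11)
  for (i in 1:1000) {
    p_a <- random_partition(markers)
    p_b <- random_partition(markers)
    if (max(p_a) == 0) next
    got <- suppressMessages(module_preservation(p_a, p_b))
    expect_equal(unname(got), preservation_oracle(p_a, p_b),
                 tolerance = 1e-12)
  }
})

test_that("Fisher meta-analysis matches closed forms and is monotone", {
  expect_equal(fisher_meta(1), 1)
  expect_equal(fisher_meta(c(1, 1, 1)), 1)
  expect_equal(fisher_meta(0.2), 0.2)          # k = 1 identity
  # df = 4 closed form: p = exp(-x/2) * (1 + x/2)
  x2 <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(x2, 11.98, tolerance = 1e-3)
  expect_equal(fisher_meta(c(0.05, 0.05)), exp(-x2 / 2) * (1 + x2 / 2))
  expect_equal(fisher_meta(c(0.05, 0.05)), 0.01748, tolerance = 1e-3)
  expect_warning(p0 <- fisher_meta(c(0, 0.5), zero_sub = 1e-4), "clamped")
  expect_true(p0 > 0)
  expect_error(fisher_meta(numeric(0)), "empty")
  set.seed(31)
  for (i in 1:50) {
    p <- runif(4)
    j <- sample(4, 1)
    p2 <- p; p2[j] <- p[j] / 2
    expect_lte(fisher_meta(p2), fisher_meta(p))
  }
})

test_that("self-comparison gives full preservation and p = 1", {
  co <- simulate_cohort(sim_config(seed = 19, missing_rate = 0))
  pt <- preservation_permutation_test(co$expression, "CRS0", "CRS0",
                                      sex = "M", n_perm = 200, seed = 4)
  expect_true(all(pt$observed == 1))
  expect_true(all(pt$p_module == 1))
  expect_equal(pt$fisher_p, 1, tolerance = 1e-12)
})

test_that("the add-one empirical p attains its floor and the test is seeded", {
  co <- simulate_cohort(sim_config(seed = 23, missing_rate = 0))
  pt1 <- preservation_permutation_test(co$expression, "CRS0", "CRS35",
                                       sex = "F", n_perm = 300, seed = 9)
  pt2 <- preservation_permutation_test(co$expression, "CRS0", "CRS35",
                                       sex = "F", n_perm = 300, seed = 9)
  expect_identical(pt1$p_module, pt2$p_module)
  expect_identical(pt1$null, pt2$null)
  expect_true(all(pt1$p_module >= 1 / 301 - 1e-15))
  expect_true(all(pt1$p_module <= 1))
  # the add-one floor: an observation below every null draw
  obs_below_all <- (0 + 1) / (10000 + 1)
  expect_equal(obs_below_all, 9.999e-5, tolerance = 1e-4)
  expect_warning(
    preservation_permutation_test(co$expression, "CRS0", "CRS7",
                                  sex = "M", n_perm = 50, seed = 1),
    "n_perm")
})

test_that("all-pairs comparison covers 15 pairs with BH-corrected q >= p", {
  co <- simulate_cohort(sim_config(seed = 29, missing_rate = 0))
  cmp <- compare_all_groups(co$expression, sex = "F", n_perm = 100,
                            seed = 3)
  expect_equal(nrow(cmp$summary), choose(6, 2))
  ok <- !is.na(cmp$summary$fisher_p)
  expect_true(all(cmp$summary$q[ok] >= cmp$summary$fisher_p[ok] - 1e-15))
  # a missing cell is skipped, not fatal
  sub <- co$expression[co$expression$group != "CRS21", ]
  expect_message(cmp2 <- compare_all_groups(sub, sex = "F", n_perm = 100,
                                            seed = 3), "skipped")
  expect_equal(nrow(cmp2$summary), choose(5, 2))
})

test_that("network export writes SIF and round-trippable GraphML", {
  co <- simulate_cohort(sim_config(seed = 37, missing_rate = 0))
  net <- build_group_network(co$expression, "CRS0", "F")
  part <- detect_modules(net)

  # empty partition: 11 isolated nodes, no edges
  none <- structure(setNames(integer(11), net$markers),
                    class = "module_partition")
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, none, sif, "SIF")
  lines <- readLines(sif)
  expect_length(lines, 11)
  expect_false(any(grepl("\t", lines)))

  # one 3-marker module: a triangle, 3 SIF edges
  tri <- none
  tri[c("GLT1", "GFAP", "GS")] <- 1L
  export_network(net, tri, sif, "SIF")
  lines <- readLines(sif)
  expect_equal(sum(grepl("\tcoexpr\t", lines)), 3)
  expect_equal(sum(!grepl("\t", lines)), 8)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, part, gml, "GraphML")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 11)
  n_intra <- sum(sapply(seq_len(max(part, 1)), function(m)
    choose(sum(part == m), 2)))
  expect_equal(igraph::ecount(g), n_intra)
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g))
    expect_equal(sort(igraph::E(g)$weight),
                 sort(net$adjacency[ends]), tolerance = 1e-6)
  }
  expect_setequal(igraph::V(g)$compartment,
                  unique(default_panel()$compartment))
})
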
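test_that("density matches the printed fixture values and the maximum", {
  expect_equal(net_density(make_paper_fixture("kirkos")), 69 / 600)
  expect_equal(net_density(make_paper_fixture("kolfe")), 101 / 650)
  full <- matrix(1L, 4, 4); diag(full) <- 0L
  expect_equal(net_density(net_from_adj(full)), 1)
  expect_error(net_density(net_from_adj(matrix(0L, 1, 1))), "at least 2")
})

test_that("degree means and per-node counts behave as defined", {
  k <- make_paper_fixture("kirkos")
  expect_equal(degree(k, "out")$mean, 69 / 25)
  expect_equal(degree(k, "in")$mean, degree(k, "out")$mean)
  expect_equal(degree(make_paper_fixture("kolfe"), "out")$mean, 101 / 26)
  # in-star: center receives from every leaf
  A <- matrix(0L, 5, 5); A[2:5, 1] <- 1L
  star <- net_from_adj(A)
  expect_equal(unname(degree(star, "in")$degrees[1]), 4L)
  expect_equal(unname(degree(star, "out")$degrees[2:5]), rep(1L, 4))
})

test_that("dyad census hand cases and fixture value", {
  A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 1] <- A[1, 3] <- 1L
  expect_equal(unname(dyad_census(net_from_adj(A))), c(1L, 1L, 1L))
  empty <- net_from_adj(matrix(0L, 5, 5))
  expect_equal(unname(dyad_census(empty)), c(0L, 0L, 10L))
  expect_equal(unname(dyad_census(make_paper_fixture("kirkos"))),
               c(9L, 51L, 240L))
})

test_that("reciprocity conventions: dyadic includes null dyads, arc mode is 2M/m", {
  expect_equal(reciprocity(make_paper_fixture("kirkos"), "dyadic"), 249 / 300)
  A2 <- matrix(0L, 2, 2); A2[1, 2] <- A2[2, 1] <- 1L
  mut <- net_from_adj(A2)
  expect_equal(reciprocity(mut, "dyadic"), 1)
  expect_equal(reciprocity(mut, "arc"), 1)
  A1 <- matrix(0L, 2, 2); A1[1, 2] <- 1L
  one <- net_from_adj(A1)
  expect_equal(reciprocity(one, "dyadic"), 0)
  expect_equal(reciprocity(one, "arc"), 0)
  expect_error(reciprocity(net_from_adj(matrix(0L, 3, 3)), "arc"), "undefined")
})

test_that("centralization: star attains 1, cycle attains 0, oracle agreement", {
  A <- matrix(0L, 5, 5); A[2:5, 1] <- 1L
  expect_equal(centralization(net_from_adj(A), "in"), 1)
  for (n in c(3, 5, 7)) {
    C <- matrix(0L, n, n)
    C[cbind(seq_len(n), c(2:n, 1))] <- 1L
    expect_equal(centralization(net_from_adj(C), "in"), 0)
    expect_equal(centralization(net_from_adj(C), "out"), 0)
    expect_equal(centralization(net_from_adj(C), "total"), 0)
  }
  set.seed(11)
  for (rep in 1:25) {
    A <- rand_adj(6, runif(1, 0.1, 0.8))
    net <- net_from_adj(A)
    for (mode in c("in", "out", "total")) {
      expect_equal(centralization(net, mode), oracle_centralization(A, mode))
      expect_gte(centralization(net, mode), 0)
      expect_lte(centralization(net, mode), 1)
    }
  }
})

test_that("centralization attains 1 only on the matching star (n = 3..8)", {
  for (n in 3:8) {
    A <- matrix(0L, n, n); A[2:n, 1] <- 1L   # in-star
    net <- net_from_adj(A)
    expect_equal(centralization(net, "in"), 1)
    expect_lt(centralization(net, "out"), 1)
    Am <- matrix(0L, n, n); Am[2:n, 1] <- 1L; Am[1, 2:n] <- 1L  # mutual star
    expect_equal(centralization(net_from_adj(Am), "total"), 1)
  }
})

test_that("mixing matrix counts arcs by category and sums to m", {
  one_cat <- net_from_adj(rand_adj(4, 0.5), orgs = toy_orgs(4, rep("ngo", 4)))
  M <- mixing_matrix(one_cat, "org_type")
  expect_equal(dim(M), c(1, 1))
  expect_equal(sum(M), n_arcs(one_cat))

  orgs <- toy_orgs(3, c("fbo", "fbo", "ngo"))
  A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 1] <- 1L
  net <- net_from_adj(A, orgs = orgs)
  M2 <- mixing_matrix(net, "org_type")
  expect_equal(M2["fbo", "fbo"], 2)
  expect_equal(sum(M2) - M2["fbo", "fbo"], 0)

  kir <- make_paper_fixture("kirkos")
  M3 <- mixing_matrix(kir, "org_type")
  expect_gte(M3["fbo", "fbo"], 12)      # the four-FBO clique alone
  expect_equal(sum(M3), 69)
  rowshare <- mixing_matrix(kir, "org_type", normalize = "row")
  expect_true(all(abs(rowSums(rowshare)[rowSums(M3) > 0] - 1) < 1e-12))
  expect_error(mixing_matrix(kir, "nonexistent"), "unknown attribute")
})

test_that("summary is internally consistent on fixtures and degenerate inputs", {
  for (sc in c("kirkos", "kolfe")) {
    s <- summary(make_paper_fixture(sc))
    dc <- s$dyad_census
    expect_equal(sum(dc), s$n * (s$n - 1) / 2)
    expect_equal(2 * dc[["mutual"]] + dc[["asymmetric"]], s$m)
    expect_equal(s$density * s$n * (s$n - 1), s$m)
    expect_equal(s$mean_in_degree, s$mean_out_degree)
  }
  s0 <- summary(net_from_adj(matrix(0L, 3, 3)))
  expect_equal(s0$density, 0)
  expect_equal(s0$reciprocity_dyadic, 1)
  expect_equal(s0$centralization, 0)
  expect_true(is.na(s0$reciprocity_arc))
})

test_that("metrics agree with igraph on the fixtures", {
  skip_if_not_installed("igraph")
  for (sc in c("kirkos", "kolfe")) {
    net <- make_paper_fixture(sc)
    g <- igraph::graph_from_data_frame(net$arcs[1:2], directed = TRUE,
                                       vertices = net$organizations["org_id"])
    expect_equal(net_density(net), igraph::edge_density(g))
    dc <- igraph::dyad_census(g)
    expect_equal(unname(dyad_census(net)),
                 c(dc$mut, dc$asym, dc$null))
    expect_equal(unname(degree(net, "in")$degrees),
                 unname(igraph::degree(g, mode = "in")))
    expect_equal(centralization(net, "in"),
                 igraph::centr_degree(g, mode = "in", loops = FALSE)$centralization)
  }
})
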
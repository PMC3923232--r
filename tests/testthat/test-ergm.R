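# full-statistic evaluation used to validate change statistics: s_t(G)
full_stats <- function(A, orgs, terms, covmats = list()) {
  n <- nrow(A)
  vapply(terms, function(tm) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || A[i, j] == 0) next
      s <- s + switch(tm$kind,
        edges = 1,
        nodematch = as.numeric(orgs[[tm$attr]][i] == orgs[[tm$attr]][j]),
        nodemix = as.numeric(orgs[[tm$attr]][i] == tm$from &
                               orgs[[tm$attr]][j] == tm$to),
        absdiff = abs(orgs[[tm$attr]][i] - orgs[[tm$attr]][j]),
        nodeocov = orgs[[tm$attr]][i],
        nodeicov = orgs[[tm$attr]][j],
        edgecov = tm$m[i, j])
    }
    s
  }, numeric(1))
}

test_that("change statistics match brute-force s(G+) - s(G-) on random graphs", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 5
    orgs <- toy_orgs(n, org_type = sample(c("ngo", "fbo"), n, replace = TRUE))
    D <- matrix(runif(n * n), n, n); D <- (D + t(D)) / 2; diag(D) <- 0
    terms <- list(edges(), nodematch("org_type"),
                  nodemix("org_type", "ngo", "fbo"),
                  absdiff("clients_per_month"),
                  nodeocov("clients_per_month"),
                  nodeicov("clients_per_month"), edgecov(D))
    A <- rand_adj(n, 0.4)
    net <- net_from_adj(A, orgs = orgs)
    cs <- change_statistics(net, terms)
    for (d in seq_len(nrow(cs$dyads))) {
      i <- match(cs$dyads$source[d], orgs$org_id)
      j <- match(cs$dyads$target[d], orgs$org_id)
      Ap <- A; Ap[i, j] <- 1L
      Am <- A; Am[i, j] <- 0L
      expect_equal(unname(cs$X[d, ]),
                   unname(full_stats(Ap, orgs, terms) -
                            full_stats(Am, orgs, terms)))
    }
  }
})

test_that("edges change statistic is 1 and nodematch is the match indicator", {
  orgs <- toy_orgs(3, c("ngo", "ngo", "fbo"))
  net <- net_from_adj(matrix(0L, 3, 3), orgs = orgs)
  cs <- change_statistics(net, list(edges(), nodematch("org_type")))
  expect_true(all(cs$X[, "edges"] == 1))
  d12 <- which(cs$dyads$source == "T01" & cs$dyads$target == "T02")
  d13 <- which(cs$dyads$source == "T01" & cs$dyads$target == "T03")
  expect_equal(unname(cs$X[d12, "nodematch.org_type"]), 1)
  expect_equal(unname(cs$X[d13, "nodematch.org_type"]), 0)
})

test_that("edges-only pseudolikelihood equals logit of density in closed form", {
  k <- make_paper_fixture("kirkos")
  fit <- ergm_mple(k ~ edges())
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), log(0.115 / 0.885), tolerance = 1e-8)
})

test_that("MPLE matches an independent logistic solver on the same design", {
  set.seed(23)
  for (rep in 1:5) {
    net <- random_network(20, list(edges(), nodematch("org_type")),
                          c(-1.5, 0.7), seed = 100 + rep)
    fit <- ergm_mple(net ~ edges() + nodematch("org_type"))
    cs <- change_statistics(net, list(edges(), nodematch("org_type")))
    ref <- stats::glm.fit(cs$X, cs$y, family = stats::binomial())
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)), unname(ref$coefficients), tolerance = 1e-6)
    se_ref <- sqrt(diag(chol2inv(qr.R(ref$qr))))
    expect_equal(unname(fit$se), se_ref, tolerance = 1e-4)
  }
})

test_that("separation is flagged, not silently reported as converged", {
  # pure homophily: arcs exist only within category, every cross dyad empty
  orgs <- toy_orgs(6, rep(c("ngo", "fbo"), each = 3))
  A <- matrix(0L, 6, 6)
  A[1:3, 1:3] <- 1L; A[4:6, 4:6] <- 1L; diag(A) <- 0L
  net <- net_from_adj(A, orgs = orgs)
  expect_warning(fit <- ergm_mple(net ~ edges() + nodematch("org_type")),
                 "converge")
  expect_false(fit$converged)
  expect_true(fit$separation)
})

test_that("rank-deficient designs are rejected with an error", {
  orgs <- toy_orgs(4, rep("ngo", 4))
  net <- net_from_adj(rand_adj(4, 0.5), orgs = orgs)
  expect_error(ergm_mple(net ~ edges() + nodematch("org_type")),
               "rank deficient")
})

test_that("formula and term-list interfaces agree; methods are coherent", {
  k <- make_paper_fixture("kirkos")
  f1 <- ergm_mple(k ~ edges() + nodematch("org_type"))
  f2 <- ergm_mple(k, terms = list(edges(), nodematch("org_type")))
  expect_equal(coef(f1), coef(f2))
  expect_equal(unname(diag(vcov(f1))), unname(f1$se^2))
  expect_equal(as.numeric(logLik(f1)), f1$logLik)
  p <- predict(f1)
  expect_equal(length(p), 600)
  expect_true(all(p > 0 & p < 1))
  expect_equal(predict(f1, type = "link"), qlogis(p))
  r <- residuals(f1, "pearson")
  expect_equal(length(r), 600)
  expect_equal(sum(f1$y), 69)               # observed arcs carried through
  expect_output(print(summary(f1)), "pseudolikelihood")
})

test_that("Metropolis simulation is reproducible and hits closed-form means", {
  k <- make_paper_fixture("kirkos")
  s1 <- simulate_ergm(k, list(edges()), -2, n_samples = 3, seed = 42)
  s2 <- simulate_ergm(k, list(edges()), -2, n_samples = 3, seed = 42)
  expect_identical(lapply(s1, `[[`, "arcs"), lapply(s2, `[[`, "arcs"))

  sims0 <- simulate_ergm(k, list(edges()), 0, n_samples = 200, seed = 7)
  expect_equal(mean(sapply(sims0, net_density)), 0.5, tolerance = 0.02 / 0.5)

  simsk <- simulate_ergm(k, list(edges()), qlogis(0.115),
                         n_samples = 200, seed = 8)
  expect_lt(abs(mean(sapply(simsk, n_arcs)) - 69), 3)
  expect_error(simulate_ergm(k, list(edges()), Inf), "finite")
})

test_that("simulate method on a fit draws from the fitted model", {
  k <- make_paper_fixture("kirkos")
  fit <- ergm_mple(k ~ edges())
  sims <- simulate(fit, nsim = 100, seed = 5)
  expect_equal(mean(sapply(sims, n_arcs)), 69, tolerance = 0.05)
})

test_that("homophily report screens attributes and flags degeneracies", {
  k <- make_paper_fixture("kirkos")
  rep_tab <- homophily_report(k, attrs = c("org_type", "subcity"),
                              covariates = list(distance = distance_matrix(k)))
  expect_equal(nrow(rep_tab), 3)
  # the planted FBO clique forces positive type homophily
  expect_gt(rep_tab$estimate[rep_tab$term == "nodematch.org_type"], 0)
  # single-category attribute is degenerate, not fitted
  expect_true(rep_tab$degenerate[rep_tab$term == "nodematch.subcity"])
  expect_true(is.na(rep_tab$estimate[rep_tab$term == "nodematch.subcity"]))
})
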
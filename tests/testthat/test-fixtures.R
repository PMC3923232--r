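test_that("the Kirkos fixture reproduces every printed marginal constraint", {
  k <- make_paper_fixture("kirkos")
  expect_equal(n_orgs(k), 25)
  expect_equal(n_arcs(k), 69)
  tt <- table(k$organizations$org_type)
  expect_equal(as.integer(tt[c("gov_health_center", "ngo", "fbo", "private_clinic")]),
               c(3L, 14L, 6L, 2L))
  svc <- org_services(k)
  fp_providers <- names(svc)[vapply(svc, function(s) "fp" %in% s, logical(1))]
  expect_equal(length(fp_providers), 7)           # both-service orgs
  expect_equal(sum(!names(svc) %in% fp_providers), 18)  # HIV-only: 72%
  expect_equal(unname(dyad_census(k)), c(9L, 51L, 240L))
  expect_equal(net_density(k), 0.115)
  expect_equal(reciprocity(k), 0.83)
  expect_equal(degree(k, "out")$mean, 2.76)
  expect_equal(median(k$organizations$clients_per_month), 219)
  expect_equal(median(k$organizations$clinical_staff), 10)
  expect_equal(median(k$organizations$nonclinical_staff), 2)

  # the four-FBO clique: all 12 intra-clique arcs, exactly one arc out
  A <- adjacency(k)
  clique <- c("K18", "K19", "K20", "K21")
  expect_true(all(k$organizations[k$organizations$org_id %in% clique,
                                  "org_type"] == "fbo"))
  expect_equal(sum(A[clique, clique]), 12L)
  expect_equal(sum(A[clique, setdiff(colnames(A), clique)]), 1L)

  # exactly 2 HIV-only orgs with no referral to an FP provider, 16 with one
  hiv_only <- setdiff(names(svc), fp_providers)
  has_fp_arc <- vapply(hiv_only, function(i)
    any(A[i, fp_providers] == 1L), logical(1))
  expect_equal(sum(!has_fp_arc), 2L)
  expect_equal(sum(has_fp_arc), 16L)
})

test_that("the Kolfe fixture reproduces every printed marginal constraint", {
  l <- make_paper_fixture("kolfe")
  expect_equal(n_orgs(l), 26)
  expect_equal(n_arcs(l), 101)
  tt <- table(l$organizations$org_type)
  expect_equal(as.integer(tt[c("gov_hospital", "gov_health_center", "gov_health_post",
                              "ngo", "fbo", "private_clinic", "private_hospital")]),
               c(1L, 3L, 3L, 6L, 1L, 10L, 2L))
  svc <- org_services(l)
  has_fp <- vapply(svc, function(s) "fp" %in% s, logical(1))
  has_hiv <- vapply(svc, function(s) any(s != "fp"), logical(1))
  expect_equal(sum(has_fp & has_hiv), 20)   # both: 77%
  expect_equal(sum(!has_fp), 5)             # HIV-only (Table 1 arithmetic)
  expect_equal(sum(has_fp & !has_hiv), 1)   # FP-only
  expect_equal(unname(dyad_census(l)), c(15L, 71L, 239L))
  expect_equal(round(net_density(l), 3), 0.155)
  expect_equal(round(reciprocity(l), 2), 0.78)
  expect_equal(round(degree(l, "out")$mean, 2), 3.88)
  expect_equal(median(l$organizations$clients_per_month), 1350)
  hosp <- l$organizations$org_id[l$organizations$org_type == "gov_hospital"]
  expect_equal(l$organizations$clients_per_month[
    l$organizations$org_id == hosp], 150000L)
  A <- adjacency(l)
  expect_gte(sum(A[, hosp]), 12)            # received-ties hub
  # every non-FP organization refers to at least one FP provider
  fp_providers <- names(svc)[has_fp]
  for (i in names(svc)[!has_fp]) {
    expect_true(any(A[i, fp_providers] == 1L))
  }
})

test_that("fixture centralizations fall in the soft band around the printed values", {
  expect_lt(abs(centralization(make_paper_fixture("kirkos"), "in") - 0.192), 0.05)
  expect_lt(abs(centralization(make_paper_fixture("kolfe"), "in") - 0.525), 0.05)
})

test_that("fixture generation is deterministic, down to written bytes", {
  k1 <- make_paper_fixture("kirkos")
  k2 <- make_paper_fixture("kirkos")
  expect_identical(k1, k2)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  p1 <- write_fixture_files("kolfe", d1)
  p2 <- write_fixture_files("kolfe", d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
})

test_that("nomination fixtures recover the roster exactly and exercise both rule paths", {
  for (sc in c("kirkos", "kolfe")) {
    net <- make_paper_fixture(sc)
    fx <- nomination_fixture(net, seed = 1)
    roster <- build_roster(fx$seeds, fx$nominations, fx$private_clinics)
    expect_equal(roster, sort(net$organizations$org_id))

    # the non-private distractor named once is excluded
    expect_false(fx$distractors %in% roster)
    # ... but a once-named private clinic distractor is included
    noms2 <- rbind(fx$nominations,
                   data.frame(nominator = fx$seeds[1], nominee = "ZPRIV1"))
    roster2 <- build_roster(fx$seeds, noms2,
                            c(fx$private_clinics, "ZPRIV1"))
    expect_equal(length(roster2), n_orgs(net) + 1)
    expect_true("ZPRIV1" %in% roster2)
  }
})

test_that("random networks are seed-reproducible and hit the target density", {
  r1 <- random_network(15, list(edges()), -1.5, seed = 11)
  r2 <- random_network(15, list(edges()), -1.5, seed = 11)
  expect_identical(r1, r2)
  validate_network(r1)

  theta <- qlogis(0.115)
  dens <- vapply(1:200, function(s)
    net_density(random_network(25, list(edges()), theta, seed = s)),
    numeric(1))
  expect_equal(mean(dens), 0.115, tolerance = 0.01 / 0.115)
})

test_that("a positive homophily coefficient inflates the mixing-matrix diagonal", {
  terms <- list(edges(), nodematch("org_type"))
  hits <- 0L
  n_draws <- 40L
  for (s in seq_len(n_draws)) {
    net <- random_network(25, terms, c(-2.5, 1.5), seed = 300 + s)
    if (n_arcs(net) == 0) next
    M <- mixing_matrix(net, "org_type")
    diag_share <- sum(diag(M)) / sum(M)
    # attribute-frequency expectation of the diagonal share under no homophily
    p <- table(net$organizations$org_type)
    exp_share <- sum(p * (p - 1)) / (sum(p) * (sum(p) - 1))
    if (diag_share > exp_share) hits <- hits + 1L
  }
  expect_gte(hits / n_draws, 0.95)
})
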
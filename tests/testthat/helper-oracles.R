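# Independent brute-force oracles and tiny generators used across the suite.
# Every oracle works from an adjacency matrix with explicit loops or direct
# enumeration -- none shares code with the package implementations.

toy_orgs <- function(n, org_type = rep("ngo", n), services = rep("hiv_testing", n),
                     subcity = "T", management = NULL) {
  if (is.null(management)) {
    management <- c(gov_hospital = "government", gov_health_center = "government",
                    gov_health_post = "government", ngo = "board",
                    fbo = "religious", private_clinic = "owner",
                    private_hospital = "owner")[org_type]
  }
  data.frame(org_id = sprintf("T%02d", seq_len(n)),
             name = sprintf("T%02d", seq_len(n)), subcity = subcity,
             org_type = org_type, management = unname(management),
             services = services, clients_per_month = seq_len(n) * 10L,
             clinical_staff = 2L, nonclinical_staff = 1L,
             x = as.numeric(seq_len(n)), y = 0,
             stringsAsFactors = FALSE)
}

net_from_adj <- function(A, orgs = NULL, ...) {
  n <- nrow(A)
  if (is.null(orgs)) orgs <- toy_orgs(n, ...)
  ids <- orgs$org_id
  idx <- which(A == 1, arr.ind = TRUE)
  referral_network(orgs, data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                                    stringsAsFactors = FALSE))
}

rand_adj <- function(n, p = 0.3) {
  A <- matrix(as.integer(runif(n * n) < p), n, n)
  diag(A) <- 0L
  A
}

# ---- metric oracles (explicit loops) ----------------------------------------

oracle_density <- function(A) {
  n <- nrow(A); m <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && A[i, j] == 1) m <- m + 1L
  m / (n * (n - 1))
}

oracle_dyad_census <- function(A) {
  n <- nrow(A); M <- 0L; As <- 0L; N <- 0L
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    s <- A[i, j] + A[j, i]
    if (s == 2) M <- M + 1L else if (s == 1) As <- As + 1L else N <- N + 1L
  }
  c(M, As, N)
}

oracle_reciprocity <- function(A, mode = "dyadic") {
  dc <- oracle_dyad_census(A)
  if (mode == "dyadic") (dc[1] + dc[3]) / sum(dc) else 2 * dc[1] / sum(A)
}

oracle_centralization <- function(A, mode = "in") {
  n <- nrow(A)
  d <- numeric(n)
  for (i in seq_len(n)) {
    din <- sum(A[, i]); dout <- sum(A[i, ])
    d[i] <- switch(mode, "in" = din, "out" = dout, "total" = din + dout)
  }
  denom <- switch(mode, "in" = (n - 1)^2, "out" = (n - 1)^2,
                  "total" = (n - 1) * (2 * n - 4))
  s <- 0
  for (i in seq_len(n)) s <- s + max(d) - d[i]
  s / denom
}

# all 2^(n(n-1)) adjacency matrices on n nodes (row-major off-diagonal bits)
all_digraphs <- function(n) {
  nd <- n * (n - 1)
  off <- which(matrix(TRUE, n, n) & !diag(TRUE, n), arr.ind = TRUE)
  off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
  lapply(seq_len(2^nd) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(nd)]
    A <- matrix(0L, n, n)
    A[off] <- bits
    A
  })
}

# ---- gap oracle: direct set logic over orgs x domains -----------------------

oracle_gap_flags <- function(net, catalogue = service_catalogue(),
                             mode = "domain") {
  svc <- org_services(net)
  ids <- net$organizations$org_id
  A <- adjacency(net)
  flags <- character()
  for (dom in names(catalogue)) {
    codes <- catalogue[[dom]]
    for (i in seq_along(ids)) {
      own <- intersect(svc[[i]], codes)
      if (mode == "domain") {
        if (length(own) > 0) next
        covered <- FALSE
        for (j in seq_along(ids)) {
          if (A[i, j] == 1 && length(intersect(svc[[j]], codes)) > 0) covered <- TRUE
        }
        if (!covered) flags <- c(flags, paste(ids[i], dom))
      } else {
        if (length(own) == 0 || all(codes %in% svc[[i]])) next
        covered <- FALSE
        for (j in seq_along(ids)) {
          if (j != i && A[i, j] == 1 &&
              length(intersect(svc[[j]], codes)) > 0) covered <- TRUE
        }
        if (!covered) flags <- c(flags, paste(ids[i], dom))
      }
    }
  }
  sort(flags)
}

# ---- roster brute-force oracle ----------------------------------------------

oracle_roster <- function(seeds, noms, private_ids) {
  # reachability by repeated scanning
  reached <- seeds
  repeat {
    new <- unique(noms$nominee[noms$nominator %in% reached])
    new <- setdiff(new, reached)
    if (!length(new)) break
    reached <- c(reached, new)
  }
  ok <- character()
  for (id in reached) {
    namers <- unique(noms$nominator[noms$nominee == id &
                                      noms$nominator %in% reached])
    k <- length(namers)
    if (id %in% seeds || k >= 2 || (id %in% private_ids && k >= 1)) {
      ok <- c(ok, id)
    }
  }
  sort(ok)
}

# ---- exhaustive ERGM likelihood on tiny graphs ------------------------------

# exact MLE for dyad-level statistics by maximising the true likelihood
# theta . s(obs) - log sum_G exp(theta . s(G)) over all digraphs on n nodes
oracle_exhaustive_mle <- function(A_obs, stat_fun, start = c(0, 0)) {
  n <- nrow(A_obs)
  graphs <- all_digraphs(n)
  S <- t(vapply(graphs, stat_fun, numeric(length(start))))
  s_obs <- stat_fun(A_obs)
  negll <- function(theta) {
    lin <- S %*% theta
    mx <- max(lin)
    -(sum(s_obs * theta) - (mx + log(sum(exp(lin - mx)))))
  }
  stats::optim(start, negll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))$par
}
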
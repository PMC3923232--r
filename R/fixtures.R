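#' Deterministic paper-shaped fixture networks
#'
#' The raw sociometric data behind the published two-sub-city referral study
#' are unpublished, so these synthetic stand-ins reproduce every printed
#' marginal constraint instead: organization-type counts, service mixes and
#' staffing/client medians (Table 1/2 analogues), arc counts, dyad censuses
#' and hence densities, mean degrees and reciprocities (Table 3 analogues),
#' the four-FBO clique with a single outgoing arc, the family-planning
#' referral-gap structure, and the received-ties hospital hub. Edge placement
#' is constraint-first (clique, hub, gap plan, mutual-dyad quota placed
#' explicitly) followed by seeded random fill under rejection rules, so the
#' printed counts hold exactly while the remaining structure is plausibly
#' disordered. Generation is fully deterministic: a fixed internal seed, the
#' same network on every call and platform.
#'
#' Kirkos: n = 25 (3 government health centers, 14 NGOs, 6 FBOs, 2 private
#' clinics), 18 HIV-only / 7 both-service organizations, m = 69, dyad census
#' (9, 51, 240), exactly 2 HIV-only organizations without any arc to a family
#' planning provider, median 219 clients/month. Kolfe: n = 26 (1 government
#' hospital, 3 health centers, 3 health posts, 6 NGOs, 1 FBO, 10 private
#' clinics, 2 private hospitals), 5 HIV-only / 1 FP-only / 20 both, m = 101,
#' dyad census (15, 71, 239), hospital in-degree 17 with 150000 clients/month,
#' every non-FP organization referring to at least one FP provider, median
#' 1350 clients/month.
#'
#' @param subcity `"kirkos"` or `"kolfe"`.
#' @return A validated [referral_network()].
#' @examples
#' summary(make_paper_fixture("kirkos"))
#' @export
make_paper_fixture <- function(subcity = c("kirkos", "kolfe")) {
  subcity <- match.arg(subcity)
  if (subcity == "kirkos") make_kirkos() else make_kolfe()
}

HIV_CODES <- c("hiv_testing", "hiv_art", "hiv_care_support", "hiv_pmtct")
ALL_CODES <- c("fp", HIV_CODES)

# service strings: full HIV set for 'both'; HIV-only orgs rotate through
# partial profiles so partial-coverage gap logic has something to chew on
hiv_profile <- function(k) {
  profiles <- list(HIV_CODES,
                   c("hiv_testing", "hiv_care_support"),
                   c("hiv_testing", "hiv_art", "hiv_care_support"),
                   c("hiv_care_support", "hiv_pmtct"))
  paste(sort(profiles[[(k - 1L) %% 4L + 1L]]), collapse = ";")
}

both_services <- paste(sort(ALL_CODES), collapse = ";")

# integer attribute vector of length n with the given median pinned exactly
pinned_values <- function(n, med, sdlog) {
  v <- sort(as.integer(round(stats::rlnorm(n, log(med), sdlog))))
  med <- as.integer(med)
  mid <- (n + 1L) %/% 2L
  lo <- seq_len(mid - 1L)
  hi <- seq.int(mid + 1L + (1L - n %% 2L), n)
  v[mid] <- med
  if (n %% 2L == 0L) v[mid + 1L] <- med
  v[lo] <- pmin(v[lo], med)   # keep the middle order statistic pinned
  v[hi] <- pmax(v[hi], med)
  stopifnot(stats::median(v) == med)
  sample(v)   # random assignment order, median unchanged
}

# greedy seeded placement of extra mutual dyads / asymmetric arcs under caps
place_mutual <- function(A, k, nodes, indeg_cap) {
  n <- nrow(A)
  while (k > 0L) {
    indeg <- colSums(A)
    cand <- which(outer(seq_len(n), seq_len(n), function(i, j) i < j), arr.ind = TRUE)
    ok <- cand[, 1] %in% nodes & cand[, 2] %in% nodes &
      A[cand] == 0L & A[cand[, c(2, 1), drop = FALSE]] == 0L &
      indeg[cand[, 1]] < indeg_cap[cand[, 1]] &
      indeg[cand[, 2]] < indeg_cap[cand[, 2]]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) stop("mutual-dyad placement infeasible")
    pick <- cand[sample.int(nrow(cand), 1L), ]
    A[pick[1], pick[2]] <- 1L
    A[pick[2], pick[1]] <- 1L
    k <- k - 1L
  }
  A
}

place_asym <- function(A, k, sources, indeg_cap) {
  n <- nrow(A)
  while (k > 0L) {
    indeg <- colSums(A)
    cand <- which(matrix(TRUE, n, n) & !diag(TRUE, n), arr.ind = TRUE)
    ok <- cand[, 1] %in% sources &
      A[cand] == 0L & A[cand[, c(2, 1), drop = FALSE]] == 0L &
      indeg[cand[, 2]] < indeg_cap[cand[, 2]]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) stop("asymmetric-arc placement infeasible")
    pick <- cand[sample.int(nrow(cand), 1L), ]
    A[pick[1], pick[2]] <- 1L
    k <- k - 1L
  }
  A
}

arc_index <- function(ids, src, tgt) cbind(match(src, ids), match(tgt, ids))

finish_fixture <- function(ids, A, orgs, subcity_label) {
  idx <- which(A == 1L, arr.ind = TRUE)
  arcs <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                     stringsAsFactors = FALSE)
  arcs <- arcs[order(arcs$source, arcs$target), , drop = FALSE]
  arcs$frequency <- sample(c("rarely", "sometimes", "often"), nrow(arcs),
                           replace = TRUE, prob = c(0.25, 0.45, 0.30))
  referral_network(orgs, arcs, subcity_label)
}

make_kirkos <- function() {
  with_seed(20110501L, {
    ids <- sprintf("K%02d", 1:25)
    org_type <- c(rep("gov_health_center", 3), rep("ngo", 14),
                  rep("fbo", 6), rep("private_clinic", 2))
    management <- c(rep("government", 3), rep("board", 14),
                    rep("religious", 6), rep("owner", 2))
    # both-service: the 3 health centers, 3 NGOs, 1 clique FBO (7 total);
    # the other 18 are HIV-only
    both <- c("K01", "K02", "K03", "K04", "K05", "K06", "K18")
    services <- ifelse(ids %in% both, both_services,
                       vapply(seq_along(ids), hiv_profile, character(1)))
    n <- 25L
    A <- matrix(0L, n, n, dimnames = list(ids, ids))
    clique <- c("K18", "K19", "K20", "K21")
    for (i in clique) for (j in clique) if (i != j) A[i, j] <- 1L
    A["K18", "K01"] <- 1L                       # the single arc leaving the clique
    A["K24", "K25"] <- 1L; A["K25", "K24"] <- 1L  # the two FP-gap organizations
    # each remaining HIV-only org refers to one family planning provider
    fp_need <- c(sprintf("K%02d", 7:17), "K22", "K23")
    fp_to <- c("K01", "K02", "K03", "K04", "K05", "K06")[
      (seq_along(fp_need) - 1L) %% 6L + 1L]
    A[arc_index(ids, fp_need, fp_to)] <- 1L
    # remaining mutual dyads among the health centers
    A["K01", "K02"] <- 1L; A["K02", "K01"] <- 1L
    A["K02", "K03"] <- 1L; A["K03", "K02"] <- 1L
    # K01 is the in-degree hub (7 received ties)
    A["K04", "K01"] <- 1L
    A["K05", "K01"] <- 1L
    # random fill to m = 69: no further out-arcs from the clique or the two
    # gap organizations; in-degrees capped below the hub
    sources <- which(!(ids %in% c(clique, "K24", "K25")))
    indeg_cap <- rep(6L, n); indeg_cap[1L] <- 7L
    A <- place_asym(A, 69L - sum(A), sources, indeg_cap)

    clients <- pinned_values(n, 219, 0.9)
    clinical <- pinned_values(n, 10, 0.6)
    nonclin <- pinned_values(n, 2, 0.7)
    orgs <- data.frame(
      org_id = ids,
      name = paste("Kirkos", gsub("_", " ", org_type),
                   stats::ave(seq_along(ids), org_type, FUN = seq_along)),
      subcity = "Kirkos", org_type = org_type, management = management,
      services = services, clients_per_month = clients,
      clinical_staff = clinical, nonclinical_staff = nonclin,
      x = round(stats::runif(n, 0, 10), 3), y = round(stats::runif(n, 0, 10), 3),
      stringsAsFactors = FALSE)
    finish_fixture(ids, A, orgs, "Kirkos")
  })
}

make_kolfe <- function() {
  with_seed(20110502L, {
    ids <- sprintf("L%02d", 1:26)
    org_type <- c("gov_hospital", rep("gov_health_center", 3),
                  rep("gov_health_post", 3), rep("ngo", 6),
                  rep("private_clinic", 10), "fbo", rep("private_hospital", 2))
    management <- c(rep("government", 7), rep("board", 6),
                    rep("owner", 10), "religious", rep("owner", 2))
    hiv_only <- c("L20", "L21", "L22", "L23", "L24")
    fp_only <- "L08"
    services <- ifelse(ids %in% hiv_only,
                       vapply(seq_along(ids), hiv_profile, character(1)),
                       ifelse(ids %in% fp_only, "fp", both_services))
    n <- 26L
    A <- matrix(0L, n, n, dimnames = list(ids, ids))
    # health posts and all HIV-only organizations refer to the hospital
    A[arc_index(ids, c("L05", "L06", "L07", hiv_only), "L01")] <- 1L
    # hospital and health centers exchange clients both ways
    for (hc in c("L02", "L03", "L04")) { A["L01", hc] <- 1L; A[hc, "L01"] <- 1L }
    # NGOs and one clinic also feed the hospital hub (in-degree 17)
    A[arc_index(ids, c(sprintf("L%02d", 9:13), "L14"), "L01")] <- 1L
    A["L08", "L02"] <- 1L                       # FP-only NGO covers HIV via a center
    # private clinics refer to the private hospitals
    A[arc_index(ids, c("L15", "L16", "L17", "L18"),
                c("L25", "L26", "L25", "L26"))] <- 1L
    # 12 further mutual dyads (15 total), then asymmetric fill to m = 101
    indeg_cap <- rep(10L, n); indeg_cap[1L] <- 17L
    A <- place_mutual(A, 12L, nodes = 2:26, indeg_cap = indeg_cap)
    A <- place_asym(A, 101L - sum(A), sources = 1:26, indeg_cap = indeg_cap)

    clients <- pinned_values(n, 1350, 0.8)
    clients[1L] <- 150000L                      # the general hospital
    clients <- fix_even_median(clients, 1350L)
    clinical <- pinned_values(n, 7, 0.6)
    nonclin <- pinned_values(n, 5, 0.6)
    orgs <- data.frame(
      org_id = ids,
      name = paste("Kolfe", gsub("_", " ", org_type),
                   stats::ave(seq_along(ids), org_type, FUN = seq_along)),
      subcity = "Kolfe Keranyo", org_type = org_type, management = management,
      services = services, clients_per_month = clients,
      clinical_staff = clinical, nonclinical_staff = nonclin,
      x = round(stats::runif(n, 0, 10), 3), y = round(stats::runif(n, 0, 10), 3),
      stringsAsFactors = FALSE)
    finish_fixture(ids, A, orgs, "Kolfe Keranyo")
  })
}

# re-pin an even-length median after overwriting one value
fix_even_median <- function(v, med) {
  if (stats::median(v) == med) return(v)
  ord <- order(v)
  n <- length(v)
  v[ord[n %/% 2L]] <- med
  v[ord[n %/% 2L + 1L]] <- med
  stopifnot(stats::median(v) == med)
  v
}

#' Pairwise driving-distance matrix
#'
#' Euclidean distances between the synthetic organization coordinates, as a
#' stand-in dyadic covariate for driving distance.
#'
#' @param net A [referral_network()] with coordinates.
#' @return Square symmetric matrix (km) with `org_id` dimnames, zero diagonal.
#' @export
distance_matrix <- function(net) {
  stopifnot(inherits(net, "referral_network"))
  xy <- as.matrix(net$organizations[c("x", "y")])
  if (anyNA(xy)) stop("network has organizations without coordinates")
  D <- as.matrix(stats::dist(xy))
  dimnames(D) <- list(net$organizations$org_id, net$organizations$org_id)
  D
}

#' Random attribute-and-network generator
#'
#' Samples organization attributes (type frequencies, service-mix
#' probabilities, log-normal client volumes, staffing, uniform coordinates in
#' a 10 x 10 km box) and then draws the arc set from an ERGM via
#' [simulate_ergm()]. Used for statistical tests of the fitting machinery.
#'
#' @param n Number of organizations.
#' @param terms List of [ergm-terms].
#' @param theta Coefficients, one per term; finite.
#' @param attribute_sampler Optional list overriding any of `type_probs`
#'   (named over the organization types), `service_probs` (named
#'   `hiv_only`, `fp_only`, `both`), `clients_meanlog`, `clients_sdlog`,
#'   `box` (km).
#' @param seed Integer seed; same seed, same network.
#' @param subcity_label Label for the generated network.
#' @return A [referral_network()].
#' @examples
#' net <- random_network(15, list(edges()), theta = -1.5, seed = 7)
#' n_arcs(net)
#' @export
random_network <- function(n, terms, theta, attribute_sampler = list(),
                           seed = NULL, subcity_label = "random") {
  sampler <- utils::modifyList(list(
    type_probs = c(gov_hospital = 0.04, gov_health_center = 0.12,
                   gov_health_post = 0.06, ngo = 0.38, fbo = 0.14,
                   private_clinic = 0.22, private_hospital = 0.04),
    service_probs = c(hiv_only = 0.45, fp_only = 0.05, both = 0.50),
    clients_meanlog = log(400), clients_sdlog = 1,
    box = 10), attribute_sampler)
  gen <- function() {
    org_type <- sample(names(sampler$type_probs), n, replace = TRUE,
                       prob = sampler$type_probs)
    mix <- sample(names(sampler$service_probs), n, replace = TRUE,
                  prob = sampler$service_probs)
    services <- ifelse(mix == "both", both_services,
                       ifelse(mix == "fp_only", "fp",
                              vapply(sample.int(4L, n, replace = TRUE),
                                     hiv_profile, character(1))))
    mgmt <- c(gov_hospital = "government", gov_health_center = "government",
              gov_health_post = "government", ngo = "board", fbo = "religious",
              private_clinic = "owner", private_hospital = "owner")[org_type]
    orgs <- data.frame(
      org_id = sprintf("R%03d", seq_len(n)),
      name = sprintf("Random org %d", seq_len(n)),
      subcity = subcity_label, org_type = org_type, management = unname(mgmt),
      services = services,
      clients_per_month = as.integer(round(stats::rlnorm(
        n, sampler$clients_meanlog, sampler$clients_sdlog))),
      clinical_staff = 1L + stats::rpois(n, 6),
      nonclinical_staff = stats::rpois(n, 3),
      x = round(stats::runif(n, 0, sampler$box), 3),
      y = round(stats::runif(n, 0, sampler$box), 3),
      stringsAsFactors = FALSE)
    sim_seed <- sample.int(.Machine$integer.max, 1L)
    list(orgs = orgs, sim_seed = sim_seed)
  }
  parts <- if (is.null(seed)) gen() else with_seed(seed, gen())
  simulate_ergm(parts$orgs, terms, theta, n_samples = 1L,
                seed = parts$sim_seed, subcity_label = subcity_label)[[1L]]
}

#' Nomination fixture for roster reconstruction
#'
#' Generates a snowball nomination census that exactly recovers the given
#' network's organizations under [build_roster()]: seeds are the government
#' organizations; every other organization is named by two distinct
#' already-reached nominators — except private clinics, deliberately named
#' only once to exercise the inclusion-rule exception — plus optional extra
#' nominations and one non-private distractor nominee named once, which the
#' rule must exclude.
#'
#' @param net A [referral_network()] (typically a [make_paper_fixture()]).
#' @param over_nominate Fraction of additional redundant nominations relative
#'   to the minimum census size.
#' @param seed Integer seed; the census is deterministic given it.
#' @param distractor Id of the once-named non-private distractor (set `NULL`
#'   to omit).
#' @return List with `nominations` (data frame `nominator,nominee`), `seeds`,
#'   `private_clinics` and `distractors` (character vectors).
#' @examples
#' fx <- nomination_fixture(make_paper_fixture("kirkos"), seed = 1)
#' length(build_roster(fx$seeds, fx$nominations, fx$private_clinics))
#' @export
nomination_fixture <- function(net, over_nominate = 0.25, seed = 1L,
                               distractor = "ZDISTRACT1") {
  stopifnot(inherits(net, "referral_network"))
  orgs <- net$organizations
  seeds <- orgs$org_id[startsWith(orgs$org_type, "gov_")]
  if (length(seeds) == 0L) seeds <- orgs$org_id[1:2]
  private <- orgs$org_id[orgs$org_type == "private_clinic"]
  others <- setdiff(orgs$org_id, seeds)
  with_seed(seed, {
    ord <- sample(others)
    reached <- seeds
    rows <- list()
    for (id in ord) {
      k <- if (id %in% private) 1L else 2L
      nominators <- sample(reached, min(k, length(reached)))
      rows[[length(rows) + 1L]] <- data.frame(
        nominator = nominators, nominee = id, stringsAsFactors = FALSE)
      reached <- c(reached, id)
    }
    noms <- do.call(rbind, rows)
    # seeds are named too (by non-seeds), mirroring a census
    for (s in seeds) {
      nominators <- sample(setdiff(orgs$org_id, s), 2L)
      noms <- rbind(noms, data.frame(nominator = nominators, nominee = s,
                                     stringsAsFactors = FALSE))
    }
    extra <- round(over_nominate * nrow(noms))
    while (extra > 0L) {
      a <- sample(orgs$org_id, 1L); b <- sample(setdiff(orgs$org_id, a), 1L)
      noms <- rbind(noms, data.frame(nominator = a, nominee = b,
                                     stringsAsFactors = FALSE))
      extra <- extra - 1L
    }
    noms <- unique(noms)
    distractors <- character()
    if (!is.null(distractor)) {
      noms <- rbind(noms, data.frame(nominator = seeds[1L],
                                     nominee = distractor,
                                     stringsAsFactors = FALSE))
      distractors <- distractor
    }
    rownames(noms) <- NULL
    list(nominations = noms, seeds = seeds, private_clinics = private,
         distractors = distractors)
  })
}

#' Write fixture files to a directory
#'
#' Emits `nodes.csv`, `edges.csv`, `nominations.csv` and `distances.csv` for
#' a fixture sub-city, the file layout consumed by [read_network()],
#' [read_nominations()] and the command-line helper script.
#'
#' @param subcity `"kirkos"` or `"kolfe"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of file paths.
#' @export
write_fixture_files <- function(subcity = c("kirkos", "kolfe"), dir = ".") {
  subcity <- match.arg(subcity)
  net <- make_paper_fixture(subcity)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(nodes = file.path(dir, paste0(subcity, "_nodes.csv")),
             edges = file.path(dir, paste0(subcity, "_edges.csv")),
             nominations = file.path(dir, paste0(subcity, "_nominations.csv")),
             distances = file.path(dir, paste0(subcity, "_distances.csv")))
  write_network(net, paths["nodes"], paths["edges"])
  fx <- nomination_fixture(net, seed = 1L)
  utils::write.csv(fx$nominations, paths["nominations"], row.names = FALSE)
  D <- distance_matrix(net)
  utils::write.csv(data.frame(org_id = rownames(D), D, check.names = FALSE),
                   paths["distances"], row.names = FALSE)
  invisible(paths)
}
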
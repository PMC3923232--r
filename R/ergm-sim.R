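#' Simulate referral networks from an ERGM
#'
#' Metropolis sampler over directed simple graphs: at each step a uniformly
#' chosen ordered dyad is proposed for toggling and accepted with probability
#' min(1, exp(theta . delta)) where delta is the change statistic of the
#' toggle. Since every term in the vocabulary is dyadic-independent
#' ([ergm-terms]), the change statistics are state-free and are precomputed
#' once per chain; the stationary distribution makes each arc an independent
#' Bernoulli with log-odds theta . delta(i, j) — logistic(theta_edges) for
#' the edges-only model.
#'
#' @param organizations Either a [referral_network()] (its organizations are
#'   reused, its arcs ignored) or an organization data frame as accepted by
#'   [referral_network()].
#' @param terms List of [ergm-terms].
#' @param theta Numeric coefficient vector, one per term; must be finite.
#' @param n_samples Number of networks to return.
#' @param burn_in Toggles before the first sample; default `10 * n(n-1)`.
#' @param thin Toggles between samples; default `n(n-1)`.
#' @param seed Optional integer seed; the chain is reproducible given the
#'   seed and leaves the caller's RNG state untouched.
#' @param subcity_label Label for the simulated networks.
#' @return List of `n_samples` [referral_network()] objects.
#' @examples
#' net <- make_paper_fixture("kirkos")
#' sims <- simulate_ergm(net, list(edges()), theta = -2, n_samples = 2, seed = 1)
#' sapply(sims, n_arcs)
#' @export
simulate_ergm <- function(organizations, terms, theta, n_samples = 1L,
                          burn_in = NULL, thin = NULL, seed = NULL,
                          subcity_label = "simulated") {
  if (inherits(organizations, "referral_network")) {
    orgs <- organizations$organizations
  } else {
    orgs <- as.data.frame(organizations, stringsAsFactors = FALSE)
  }
  if (inherits(terms, "ergm_term")) terms <- list(terms)
  theta <- as.numeric(theta)
  if (length(theta) != length(terms)) stop("one coefficient per term required")
  if (any(!is.finite(theta))) stop("theta must be finite")
  n <- nrow(orgs)
  if (n < 2L) stop("need at least 2 organizations")
  empty <- referral_network(orgs, data.frame(source = character(),
                                             target = character()),
                            subcity_label)
  cs <- change_statistics(empty, terms)
  eta <- drop(cs$X %*% theta)        # state-free log-odds per dyad
  ndy <- length(eta)
  if (is.null(burn_in)) burn_in <- 10L * ndy
  if (is.null(thin)) thin <- ndy
  ids <- empty$organizations$org_id

  run <- function() {
    a <- integer(ndy)                 # empty graph start
    out <- vector("list", n_samples)
    total <- burn_in + thin * (n_samples - 1L) + 1L
    ks <- sample.int(ndy, total - 1L, replace = TRUE)
    us <- stats::runif(total - 1L)
    step <- 0L
    take <- burn_in
    s <- 0L
    while (s < n_samples) {
      if (step == take) {
        s <- s + 1L
        out[[s]] <- a
        take <- take + thin
        if (s == n_samples) break
      }
      step <- step + 1L
      k <- ks[step]
      # log acceptance ratio for toggling dyad k
      la <- if (a[k] == 0L) eta[k] else -eta[k]
      if (la >= 0 || us[step] < exp(la)) a[k] <- 1L - a[k]
    }
    out
  }
  states <- if (is.null(seed)) run() else with_seed(seed, run())

  lapply(states, function(a) {
    on <- a == 1L
    arcs <- data.frame(source = cs$dyads$source[on],
                       target = cs$dyads$target[on],
                       stringsAsFactors = FALSE)
    referral_network(orgs, arcs, subcity_label)
  })
}

#' @rdname simulate_ergm
#' @param object An [ergm_mple()] fit; simulation uses its network's
#'   organizations, its terms and its fitted coefficients.
#' @param nsim Number of networks.
#' @param ... Passed on to `simulate_ergm()`.
#' @export
simulate.ergm_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  simulate_ergm(object$network, object$terms, object$coefficients,
                n_samples = nsim, seed = seed, ...)
}

#' Attribute-association screen for referral ties
#'
#' Fits one two-term model per attribute or dyadic covariate — `edges()` plus
#' `nodematch(attr)` for categorical attributes, `edges()` plus
#' `absdiff(attr)` for numeric ones, `edges()` plus `edgecov(m)` for
#' covariate matrices — and reports the Wald test of the second coefficient.
#' A term is declared "associated" when |z| > 1.96 (two-sided 5% level); no
#' multiple-testing correction is applied. Degenerate terms (constant change
#' statistic, e.g. a single-category attribute) are flagged and not fitted.
#'
#' @param net A [referral_network()].
#' @param attrs Character vector of organization attribute names.
#' @param covariates Named list of square dyadic covariate matrices (e.g.
#'   driving distances), ordered like the organizations.
#' @return Data frame with one row per term: `term`, `estimate`, `se`, `z`,
#'   `p_value`, `associated`, `degenerate`.
#' @examples
#' net <- make_paper_fixture("kirkos")
#' homophily_report(net, attrs = c("org_type", "management"))
#' @export
homophily_report <- function(net, attrs = character(), covariates = list()) {
  stopifnot(inherits(net, "referral_network"))
  rows <- list()
  add_row <- function(label, fit, degenerate = FALSE) {
    if (degenerate || is.null(fit)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        term = label, estimate = NA_real_, se = NA_real_, z = NA_real_,
        p_value = NA_real_, associated = NA, degenerate = TRUE,
        stringsAsFactors = FALSE)
    } else {
      est <- unname(fit$coefficients[2L])
      se <- unname(fit$se[2L])
      z <- est / se
      rows[[length(rows) + 1L]] <<- data.frame(
        term = label, estimate = est, se = se, z = z,
        p_value = 2 * stats::pnorm(-abs(z)),
        associated = is.finite(z) && abs(z) > 1.96 && fit$converged,
        degenerate = FALSE, stringsAsFactors = FALSE)
    }
  }
  fit_or_null <- function(term) {
    tryCatch(ergm_mple(net, terms = list(edges(), term)),
             error = function(e) NULL)
  }
  for (attr in attrs) {
    v <- node_attr(net$organizations, attr)
    term <- if (is.numeric(v)) absdiff(attr) else nodematch(attr)
    if (length(unique(v)) < 2L) {
      add_row(term$label, NULL, degenerate = TRUE)
    } else {
      add_row(term$label, fit_or_null(term))
    }
  }
  if (length(covariates)) {
    labs <- names(covariates)
    if (is.null(labs)) labs <- paste0("cov", seq_along(covariates))
    for (k in seq_along(covariates)) {
      term <- edgecov(covariates[[k]])
      term$label <- paste0("edgecov.", labs[k])
      if (stats::var(covariates[[k]][row(covariates[[k]]) !=
                                       col(covariates[[k]])]) == 0) {
        add_row(term$label, NULL, degenerate = TRUE)
      } else {
        add_row(term$label, fit_or_null(term))
      }
    }
  }
  do.call(rbind, rows)
}
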
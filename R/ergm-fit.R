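#' Fit an exponential random graph model by maximum pseudolikelihood
#'
#' Fits P(network) proportional to exp(theta . s(network)) for a set of
#' dyadic-independent terms. The pseudolikelihood is the product over ordered
#' dyads of Bernoulli likelihoods with log-odds theta . delta(i, j), where
#' delta is the change statistic; it is maximised by Newton/IRLS on the
#' observed arc indicators. Because every term in the vocabulary is
#' dyadic-independent ([ergm-terms]), the maximum pseudolikelihood estimate
#' coincides with the maximum likelihood estimate.
#'
#' For the edges-only model the estimate has the closed form
#' logit(density).
#'
#' @param formula Either a formula `net ~ edges() + nodematch("org_type") + ...`
#'   whose left-hand side evaluates to a [referral_network()], or a
#'   [referral_network()] directly (then supply `terms`).
#' @param terms List of [ergm-terms]; ignored when `formula` is a formula.
#' @param tol Convergence tolerance on the maximum absolute score (gradient);
#'   default `1e-8`.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `ergm_fit` with components `coefficients`,
#'   `se`, `vcov`, `converged`, `separation`, `n_dyads`, `logLik`, `fitted`,
#'   `terms`, `network`. Methods: `print`, `summary`, `coef`, `vcov`,
#'   `logLik`, `predict`, `residuals`, `simulate`.
#' @examples
#' net <- make_paper_fixture("kirkos")
#' fit <- ergm_mple(net ~ edges() + nodematch("org_type"))
#' summary(fit)
#' @export
ergm_mple <- function(formula, terms = NULL, tol = 1e-8, max_iter = 100L) {
  if (inherits(formula, "formula")) {
    parsed <- parse_ergm_formula(formula)
    net <- parsed$net
    terms <- parsed$terms
  } else {
    net <- formula
    if (is.null(terms)) stop("supply `terms` when not using a formula")
    if (inherits(terms, "ergm_term")) terms <- list(terms)
  }
  stopifnot(inherits(net, "referral_network"), length(terms) >= 1L)
  cs <- change_statistics(net, terms)
  X <- cs$X
  y <- cs$y
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop("design matrix is rank deficient (constant or collinear term)")
  }

  theta <- rep(0, p)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% theta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) <= tol) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) { separation <- TRUE; break }
    # dampen overshoot far from the optimum
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    theta <- theta + step
    if (max(abs(theta)) > 25) { separation <- TRUE; break }
    if (iter >= max_iter) break
  }
  eta <- drop(X %*% theta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  H <- crossprod(X * w, X)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(V), 0))
  if (separation) {
    converged <- FALSE
    warning("pseudolikelihood did not converge (separation or rank problem); ",
            "coefficients flagged as non-converged")
  }
  names(theta) <- colnames(X)
  names(se) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  structure(list(coefficients = theta, se = se, vcov = V,
                 converged = converged, separation = separation,
                 n_dyads = length(y), logLik = ll, iterations = iter,
                 fitted = mu, y = y, X = X, dyads = cs$dyads,
                 terms = terms, network = net),
            class = "ergm_fit")
}

# evaluate `net ~ edges() + nodematch("x") + ...` into network + term list
parse_ergm_formula <- function(formula) {
  env <- environment(formula)
  if (length(formula) != 3L) stop("formula needs a left-hand side network")
  net <- eval(formula[[2L]], env)
  if (!inherits(net, "referral_network")) {
    stop("left-hand side must evaluate to a referral_network")
  }
  term_env <- new.env(parent = env)
  for (f in c("edges", "nodematch", "nodemix", "absdiff",
              "nodeocov", "nodeicov", "edgecov")) {
    assign(f, get(f, envir = asNamespace("referralnet")), envir = term_env)
  }
  rhs <- formula[[3L]]
  calls <- list()
  flatten <- function(e) {
    if (is.call(e) && identical(e[[1L]], as.name("+"))) {
      flatten(e[[2L]]); flatten(e[[3L]])
    } else {
      calls[[length(calls) + 1L]] <<- e
    }
  }
  flatten(rhs)
  terms <- lapply(calls, function(cl) {
    # bare `edges` is accepted as shorthand for `edges()`
    if (is.name(cl) && as.character(cl) == "edges") return(edges())
    tm <- eval(cl, term_env)
    if (!inherits(tm, "ergm_term")) stop("not an ERGM term: ", deparse(cl))
    tm
  })
  list(net = net, terms = terms)
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat("ERGM (maximum pseudolikelihood",
      if (x$converged) "— converged)" else "— NOT converged)", "\n")
  cat("Dyads:", x$n_dyads, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.ergm_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(
    estimate = object$coefficients,
    se = object$se,
    z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    row.names = names(object$coefficients))
  structure(list(coefficients = tab, converged = object$converged,
                 separation = object$separation, n_dyads = object$n_dyads,
                 logLik = object$logLik), class = "summary.ergm_fit")
}

#' @export
print.summary.ergm_fit <- function(x, ...) {
  cat("ERGM fit by maximum pseudolikelihood\n")
  cat("Dyads:", x$n_dyads, "  logLik:", format(x$logLik, digits = 6),
      "  converged:", x$converged, "\n\n")
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.ergm_fit <- function(object, ...) object$coefficients

#' @export
vcov.ergm_fit <- function(object, ...) object$vcov

#' @export
logLik.ergm_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n_dyads, class = "logLik")
}

#' Predicted arc probabilities
#'
#' @param object An [ergm_mple()] fit.
#' @param type `"response"` (probabilities, default) or `"link"` (log-odds).
#' @param ... Ignored.
#' @return Numeric vector, one entry per ordered dyad (see `object$dyads`).
#' @export
predict.ergm_fit <- function(object, type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- drop(object$X %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.ergm_fit <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  mu <- object$fitted
  y <- object$y
  if (type == "pearson") {
    (y - mu) / sqrt(mu * (1 - mu))
  } else {
    d <- -2 * (y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    sign(y - mu) * sqrt(d)
  }
}
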
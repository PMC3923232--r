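#' Detect service-referral gaps
#'
#' A service gap is an instance in which an organization could have, but did
#' not, refer clients for services it does not itself provide. Two rules are
#' implemented, per service domain of the catalogue:
#'
#' * `"domain"` mode: an organization is flagged for domain D when it provides
#'   *no* code of D and has no out-arc to any organization providing a code of
#'   D. Any out-arc to a qualifying provider clears the flag, regardless of
#'   the surveyed referral frequency.
#' * `"partial"` mode: an organization is flagged for D when it provides a
#'   nonempty *strict subset* of D's codes (e.g. "few HIV services") and has
#'   no out-arc to any *other* organization providing any code of D.
#'
#' @param net A [referral_network()] with services populated.
#' @param catalogue A [service_catalogue()].
#' @param mode `"domain"` (default) or `"partial"`.
#' @return Data frame of class `gap_records`, one row per (organization,
#'   domain) pair to which the rule applies, with columns `org_id`,
#'   `service_domain`, `provided_codes` (semicolon-joined), `n_qualifying_targets`
#'   (out-neighbours providing the missing codes) and `flagged`.
#' @examples
#' net <- make_paper_fixture("kirkos")
#' gp <- detect_gaps(net)
#' subset(gp, flagged)
#' @export
detect_gaps <- function(net, catalogue = service_catalogue(),
                        mode = c("domain", "partial")) {
  stopifnot(inherits(net, "referral_network"))
  mode <- match.arg(mode)
  svc <- org_services(net)
  ids <- net$organizations$org_id
  A <- adjacency(net)
  rows <- list()
  for (dom in names(catalogue)) {
    codes <- catalogue[[dom]]
    provides_any <- vapply(svc, function(s) length(intersect(s, codes)) > 0L,
                           logical(1))
    provides_all <- vapply(svc, function(s) all(codes %in% s), logical(1))
    for (i in seq_along(ids)) {
      own <- intersect(svc[[i]], codes)
      applies <- if (mode == "domain") length(own) == 0L
                 else length(own) > 0L && !provides_all[[i]]
      if (!applies) next
      out_nb <- which(A[i, ] == 1L)
      qualifying <- if (mode == "domain") {
        out_nb[provides_any[out_nb]]
      } else {
        out_nb[provides_any[out_nb] & out_nb != i]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        org_id = ids[i], service_domain = dom,
        provided_codes = paste(sort(own), collapse = ";"),
        n_qualifying_targets = length(qualifying),
        flagged = length(qualifying) == 0L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    org_id = character(), service_domain = character(),
    provided_codes = character(), n_qualifying_targets = integer(),
    flagged = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gap_records", "data.frame")
  out
}

#' Referral-nature grid
#'
#' The audit grid behind visual gap identification: a square character table
#' over organizations where cell (i, j) — nonempty only where the arc i -> j
#' exists — lists the service domains that organization i needs (provides no
#' code of) and that organization j can cover. Scanning row i for a domain
#' label reproduces the domain-mode flag of [detect_gaps()]: i is flagged for
#' D exactly when i needs D and D appears in no cell of row i.
#'
#' @inheritParams detect_gaps
#' @return Character matrix with `org_id` dimnames; `""` for absent arcs and
#'   for arcs covering no needed domain.
#' @export
gap_grid <- function(net, catalogue = service_catalogue()) {
  stopifnot(inherits(net, "referral_network"))
  svc <- org_services(net)
  ids <- net$organizations$org_id
  n <- length(ids)
  A <- adjacency(net)
  provides <- sapply(names(catalogue), function(dom) {
    vapply(svc, function(s) length(intersect(s, catalogue[[dom]])) > 0L,
           logical(1))
  })
  provides <- matrix(provides, nrow = n,
                     dimnames = list(ids, names(catalogue)))
  G <- matrix("", n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    needed <- names(catalogue)[!provides[i, ]]
    if (!length(needed)) next
    for (j in which(A[i, ] == 1L)) {
      covered <- needed[provides[j, needed]]
      if (length(covered)) G[i, j] <- paste(covered, collapse = ";")
    }
  }
  structure(G, class = c("gap_grid", "matrix"))
}

#' @export
print.gap_grid <- function(x, ...) {
  cat("Referral-nature grid (", nrow(x), " organizations; cells list the\n",
      "needed domains of the row organization covered by the referral)\n",
      sep = "")
  print(unclass(x), quote = FALSE, ...)
  invisible(x)
}
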
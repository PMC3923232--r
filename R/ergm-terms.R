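#' ERGM term vocabulary
#'
#' Constructors for the dyadic-independent exponential random graph model
#' terms understood by [ergm_mple()] and [simulate_ergm()]. Every term's
#' change statistic for the ordered dyad (i, j) depends only on node
#' attributes or an exogenous dyadic covariate — never on the rest of the
#' graph — so maximum pseudolikelihood is the exact maximum likelihood for any
#' model built from them.
#'
#' * `edges()` — baseline arc count; change statistic 1 on every dyad.
#' * `nodematch(attr)` — homophily: 1 when sender and receiver share the
#'   attribute value.
#' * `nodemix(attr, from, to)` — one directed category pair: 1 when the
#'   sender is in `from` and the receiver in `to`.
#' * `absdiff(attr)` — |x_i - x_j| for a numeric attribute.
#' * `nodeocov(attr)` — sender (out) covariate x_i.
#' * `nodeicov(attr)` — receiver (in) covariate x_j.
#' * `edgecov(m)` — exogenous dyadic covariate matrix (e.g. driving
#'   distance); change statistic m\[i, j\].
#'
#' @param attr Name of an organization attribute column. `nodematch` accepts
#'   any column; `absdiff`, `nodeocov`, `nodeicov` require numeric columns.
#'   The derived attribute `"client_staff_ratio"`
#'   (clients_per_month / clinical_staff) is also recognised.
#' @param from,to Category values for `nodemix`.
#' @param m Square numeric matrix ordered like the network's organizations
#'   (zero diagonal), or the name under which a matrix is supplied to the
#'   fitting function.
#' @return An object of class `ergm_term`.
#' @name ergm-terms
NULL

new_ergm_term <- function(kind, label, ...) {
  structure(list(kind = kind, label = label, ...), class = "ergm_term")
}

#' @rdname ergm-terms
#' @export
edges <- function() new_ergm_term("edges", "edges")

#' @rdname ergm-terms
#' @export
nodematch <- function(attr) {
  new_ergm_term("nodematch", paste0("nodematch.", attr), attr = attr)
}

#' @rdname ergm-terms
#' @export
nodemix <- function(attr, from, to) {
  new_ergm_term("nodemix", paste0("mix.", attr, ".", from, ".", to),
                attr = attr, from = from, to = to)
}

#' @rdname ergm-terms
#' @export
absdiff <- function(attr) {
  new_ergm_term("absdiff", paste0("absdiff.", attr), attr = attr)
}

#' @rdname ergm-terms
#' @export
nodeocov <- function(attr) {
  new_ergm_term("nodeocov", paste0("nodeocov.", attr), attr = attr)
}

#' @rdname ergm-terms
#' @export
nodeicov <- function(attr) {
  new_ergm_term("nodeicov", paste0("nodeicov.", attr), attr = attr)
}

#' @rdname ergm-terms
#' @export
edgecov <- function(m) {
  label <- if (is.character(m)) m else deparse(substitute(m))[1]
  new_ergm_term("edgecov", paste0("edgecov.", label), m = m)
}

#' @export
print.ergm_term <- function(x, ...) {
  cat("<ergm term>", x$label, "\n")
  invisible(x)
}

# numeric or categorical attribute lookup, incl. the derived staff ratio
node_attr <- function(organizations, attr) {
  if (attr == "client_staff_ratio") {
    cs <- organizations$clinical_staff
    return(organizations$clients_per_month / ifelse(cs > 0, cs, NA_real_))
  }
  if (!attr %in% names(organizations)) stop("attribute not found: ", attr)
  organizations[[attr]]
}

#' Change statistics for a set of ERGM terms
#'
#' One row per ordered dyad (i, j), i != j, in row-major organization order;
#' one column per term. Entry (d, t) is the difference in network statistic t
#' caused by adding the arc of dyad d to the graph with that arc absent,
#' holding all other arcs fixed. Because every implemented term is
#' dyadic-independent, the value depends only on the endpoint attributes (or
#' the covariate matrix) and not on the current graph.
#'
#' @param net A [referral_network()].
#' @param terms A list of [ergm-terms], or a single term.
#' @return List with `X` (numeric matrix, n(n-1) x n_terms, columns named by
#'   term labels), `dyads` (data frame `source`, `target`) and `y` (0/1
#'   observed-arc indicator for each dyad).
#' @examples
#' net <- make_paper_fixture("kirkos")
#' cs <- change_statistics(net, list(edges(), nodematch("org_type")))
#' head(cs$X)
#' @export
change_statistics <- function(net, terms) {
  stopifnot(inherits(net, "referral_network"))
  if (inherits(terms, "ergm_term")) terms <- list(terms)
  stopifnot(length(terms) >= 1L, all(vapply(terms, inherits, TRUE, "ergm_term")))
  orgs <- net$organizations
  ids <- orgs$org_id
  n <- length(ids)
  if (n < 2L) stop("need at least 2 organizations")
  pair <- which(matrix(TRUE, n, n) & !diag(TRUE, n), arr.ind = TRUE)
  # row-major order: all dyads (1,j), then (2,j), ...
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
  i <- pair[, 1]; j <- pair[, 2]
  X <- matrix(NA_real_, length(i), length(terms))
  colnames(X) <- vapply(terms, `[[`, character(1), "label")
  for (t in seq_along(terms)) {
    tm <- terms[[t]]
    X[, t] <- switch(tm$kind,
      edges = 1,
      nodematch = {
        v <- as.character(node_attr(orgs, tm$attr))
        as.numeric(v[i] == v[j])
      },
      nodemix = {
        v <- as.character(node_attr(orgs, tm$attr))
        as.numeric(v[i] == tm$from & v[j] == tm$to)
      },
      absdiff = {
        v <- as.numeric(node_attr(orgs, tm$attr))
        abs(v[i] - v[j])
      },
      nodeocov = as.numeric(node_attr(orgs, tm$attr))[i],
      nodeicov = as.numeric(node_attr(orgs, tm$attr))[j],
      edgecov = {
        m <- tm$m
        if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
          stop("edgecov matrix must be ", n, " x ", n)
        }
        m[cbind(i, j)]
      },
      stop("unknown term kind: ", tm$kind))
  }
  if (anyNA(X)) stop("change statistics contain missing values (check attributes)")
  A <- adjacency(net)
  list(X = X,
       dyads = data.frame(source = ids[i], target = ids[j],
                          stringsAsFactors = FALSE),
       y = as.numeric(A[cbind(i, j)]))
}
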
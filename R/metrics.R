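#' Directed network density
#'
#' The number of arcs as a proportion of all ordered pairs, m / (n(n-1)).
#'
#' @param net A [referral_network()] with at least two organizations.
#' @return Fraction in \[0, 1\].
#' @examples
#' net_density(make_paper_fixture("kirkos"))  # 69/600 = 0.115
#' @export
net_density <- function(net) {
  stopifnot(inherits(net, "referral_network"))
  n <- n_orgs(net)
  if (n < 2L) stop("density requires at least 2 organizations")
  n_arcs(net) / (n * (n - 1L))
}

#' In- and out-degree
#'
#' Out-degree counts referrals sent, in-degree referrals received. The mean of
#' either equals m/n, so mean in-degree always equals mean out-degree.
#'
#' @inheritParams net_density
#' @param direction `"out"` (referrals sent) or `"in"` (referrals received).
#' @return List with `degrees` (named integer vector by `org_id`) and `mean`.
#' @export
degree <- function(net, direction = c("out", "in")) {
  stopifnot(inherits(net, "referral_network"))
  direction <- match.arg(direction)
  A <- adjacency(net)
  d <- if (direction == "out") rowSums(A) else colSums(A)
  list(degrees = stats::setNames(as.integer(d), rownames(A)),
       mean = n_arcs(net) / n_orgs(net))
}

#' Dyad census
#'
#' Counts of unordered pairs that are mutual (arcs both ways), asymmetric
#' (one way) and null (no arc). M + A + N = n(n-1)/2 and m = 2M + A.
#'
#' @inheritParams net_density
#' @return Named integer vector `c(mutual =, asymmetric =, null =)`.
#' @examples
#' dyad_census(make_paper_fixture("kirkos"))  # 9, 51, 240
#' @export
dyad_census <- function(net) {
  stopifnot(inherits(net, "referral_network"))
  A <- adjacency(net)
  n <- nrow(A)
  S <- A + t(A)
  up <- S[upper.tri(S)]
  c(mutual = sum(up == 2L), asymmetric = sum(up == 1L), null = sum(up == 0L))
}

#' Reciprocity of a directed network
#'
#' Two conventions are exposed. `"dyadic"` is the proportion of dyads that are
#' symmetric — mutual or null — i.e. (M + N) / (M + A + N); null dyads count
#' as symmetric under this convention. `"arc"` is the proportion of arcs that
#' are reciprocated, 2M / m (undefined when the network has no arcs).
#'
#' @inheritParams net_density
#' @param mode `"dyadic"` (default) or `"arc"`.
#' @return Fraction in \[0, 1\].
#' @examples
#' reciprocity(make_paper_fixture("kirkos"))  # 249/300 = 0.83
#' @export
reciprocity <- function(net, mode = c("dyadic", "arc")) {
  mode <- match.arg(mode)
  dc <- dyad_census(net)
  if (mode == "dyadic") {
    unname((dc["mutual"] + dc["null"]) / sum(dc))
  } else {
    m <- n_arcs(net)
    if (m == 0L) stop("arc reciprocity is undefined for an arcless network")
    unname(2 * dc["mutual"] / m)
  }
}

#' Freeman degree centralization
#'
#' Sum of differences between the maximum observed degree and each node's
#' degree, normalised by the maximum attainable sum — attained by the star of
#' the matching mode. For in- or out-degree the normaliser is (n-1)^2; for
#' total degree it is (n-1)(2n-4), the value attained by the fully mutual
#' star (centre total degree 2(n-1), leaves 2).
#'
#' @inheritParams net_density
#' @param mode Degree flavour: `"in"` (default — a received-ties hub drives
#'   it), `"out"` or `"total"`.
#' @return Fraction in \[0, 1\]; 0 for degree-regular graphs, 1 for the star.
#' @export
centralization <- function(net, mode = c("in", "out", "total")) {
  stopifnot(inherits(net, "referral_network"))
  mode <- match.arg(mode)
  n <- n_orgs(net)
  if (n < 3L) stop("centralization requires at least 3 organizations")
  A <- adjacency(net)
  d <- switch(mode, "in" = colSums(A), "out" = rowSums(A),
              "total" = rowSums(A) + colSums(A))
  D <- switch(mode, "in" = (n - 1)^2, "out" = (n - 1)^2,
              "total" = (n - 1) * (2 * n - 4))
  sum(max(d) - d) / D
}

#' Mixing matrix over a categorical attribute
#'
#' Cell (a, b) counts arcs from category-a organizations to category-b
#' organizations; the grand total equals the arc count. Row normalisation
#' turns counts into outgoing-referral shares.
#'
#' @inheritParams net_density
#' @param attribute Name of a categorical column of the organization table
#'   (e.g. `"org_type"`, `"management"`).
#' @param normalize `"none"` (counts, default) or `"row"` (shares of each
#'   source category's outgoing arcs).
#' @return Square numeric matrix with category dimnames.
#' @export
mixing_matrix <- function(net, attribute = "org_type",
                          normalize = c("none", "row")) {
  stopifnot(inherits(net, "referral_network"))
  normalize <- match.arg(normalize)
  orgs <- net$organizations
  if (!attribute %in% names(orgs)) stop("unknown attribute: ", attribute)
  vals <- orgs[[attribute]]
  if (anyNA(vals)) stop("attribute has missing values: ", attribute)
  lev <- sort(unique(as.character(vals)))
  M <- matrix(0, length(lev), length(lev), dimnames = list(source = lev, target = lev))
  if (nrow(net$arcs)) {
    src <- as.character(vals[match(net$arcs$source, orgs$org_id)])
    tgt <- as.character(vals[match(net$arcs$target, orgs$org_id)])
    tab <- table(factor(src, lev), factor(tgt, lev))
    M[] <- as.numeric(tab)
  }
  if (normalize == "row") {
    rs <- rowSums(M)
    M <- sweep(M, 1, ifelse(rs > 0, rs, 1), "/")
  }
  M
}

#' Whole-network summary
#'
#' All the relational characteristics reported for an organizational referral
#' network: size, links, density, Freeman centralization, mean in/out-degree,
#' reciprocity under both conventions, and the dyad census.
#'
#' @param object A [referral_network()] with at least 3 organizations.
#' @param centralization_mode Passed to [centralization()]; defaults to
#'   in-degree.
#' @param ... Ignored.
#' @return An object of class `network_summary` (a list).
#' @examples
#' summary(make_paper_fixture("kirkos"))
#' @export
summary.referral_network <- function(object, centralization_mode = "in", ...) {
  net <- object
  if (n_orgs(net) < 3L) stop("summary requires at least 3 organizations")
  dc <- dyad_census(net)
  m <- n_arcs(net)
  structure(list(
    subcity_label = net$subcity_label,
    n = n_orgs(net),
    m = m,
    density = net_density(net),
    centralization = centralization(net, centralization_mode),
    centralization_mode = centralization_mode,
    mean_out_degree = degree(net, "out")$mean,
    mean_in_degree = degree(net, "in")$mean,
    reciprocity_dyadic = reciprocity(net, "dyadic"),
    reciprocity_arc = if (m > 0L) reciprocity(net, "arc") else NA_real_,
    dyad_census = dc
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Relational characteristics",
      if (nzchar(x$subcity_label)) paste0("(", x$subcity_label, ")"), "\n")
  cat(sprintf("  Organizations                 %d\n", x$n))
  cat(sprintf("  Links                         %d\n", x$m))
  cat(sprintf("  Density                       %.3f\n", x$density))
  cat(sprintf("  Centralization (%s-degree)    %.3f\n",
              x$centralization_mode, x$centralization))
  cat(sprintf("  Referrals sent (out-degree)   %.2f\n", x$mean_out_degree))
  cat(sprintf("  Referrals received (in-degree) %.2f\n", x$mean_in_degree))
  cat(sprintf("  Reciprocity (dyadic)          %.2f\n", x$reciprocity_dyadic))
  if (!is.na(x$reciprocity_arc))
    cat(sprintf("  Reciprocity (arc)             %.2f\n", x$reciprocity_arc))
  cat(sprintf("  Dyad census (M, A, N)         %d, %d, %d\n",
              x$dyad_census[["mutual"]], x$dyad_census[["asymmetric"]],
              x$dyad_census[["null"]]))
  invisible(x)
}
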
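#' @keywords internal
"_PACKAGE"

#' Organization type and management levels
#'
#' The closed sets of organization types and management categories recognised
#' by [referral_network()] validation.
#' @name org-levels
#' @keywords internal
NULL

ORG_TYPES <- c("gov_hospital", "gov_health_center", "gov_health_post",
               "ngo", "fbo", "private_clinic", "private_hospital")
MANAGEMENT_TYPES <- c("board", "government", "owner", "religious", "other")
FREQ_LEVELS <- c("never", "rarely", "sometimes", "often")

ORG_COLUMNS <- c("org_id", "name", "subcity", "org_type", "management",
                 "services", "clients_per_month", "clinical_staff",
                 "nonclinical_staff", "x", "y")

#' Construct a referral network
#'
#' A referral network couples a table of service-providing organizations with
#' a set of directed arcs "organization i refers clients to organization j".
#' Ties are analyzed as binary; an optional ordinal `frequency` column
#' (never/rarely/sometimes/often) is carried on arcs but ignored by all
#' metrics.
#'
#' @param organizations Data frame with columns `org_id`, `name`, `subcity`,
#'   `org_type`, `management`, `services` (semicolon-separated service codes),
#'   `clients_per_month`, `clinical_staff`, `nonclinical_staff`, and optional
#'   coordinates `x`, `y` (kilometers; `NA` when unknown).
#' @param arcs Data frame with columns `source`, `target` and optionally
#'   `frequency`. One row per ordered pair; self-referrals are rejected.
#' @param subcity_label Label for the network as a whole.
#' @param catalogue [service_catalogue()] used to validate service codes.
#' @return An object of class `referral_network`: a list with elements
#'   `organizations` (data frame, ordered by `org_id`), `arcs` (data frame)
#'   and `subcity_label`.
#' @examples
#' orgs <- data.frame(org_id = c("A", "B"), name = c("A", "B"), subcity = "S",
#'                    org_type = c("ngo", "fbo"), management = c("board", "religious"),
#'                    services = c("hiv_testing", "fp"), clients_per_month = c(10, 20),
#'                    clinical_staff = c(1, 2), nonclinical_staff = c(0, 1),
#'                    x = NA_real_, y = NA_real_)
#' net <- referral_network(orgs, data.frame(source = "A", target = "B"))
#' net
#' @export
referral_network <- function(organizations, arcs, subcity_label = "",
                             catalogue = service_catalogue()) {
  organizations <- as.data.frame(organizations, stringsAsFactors = FALSE)
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (!"x" %in% names(organizations)) organizations$x <- NA_real_
  if (!"y" %in% names(organizations)) organizations$y <- NA_real_
  missing_cols <- setdiff(ORG_COLUMNS, names(organizations))
  if (length(missing_cols)) {
    stop("organizations table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  organizations <- organizations[ORG_COLUMNS]
  for (col in c("org_id", "name", "subcity", "org_type", "management")) {
    organizations[[col]] <- as.character(organizations[[col]])
  }
  for (col in c("clients_per_month", "clinical_staff", "nonclinical_staff")) {
    organizations[[col]] <- as.integer(organizations[[col]])
  }
  for (col in c("x", "y")) organizations[[col]] <- as.numeric(organizations[[col]])
  organizations$services <- canonical_services(organizations$services)
  if (nrow(arcs) && !all(c("source", "target") %in% names(arcs))) {
    stop("arcs table needs `source` and `target` columns")
  }
  if (!"frequency" %in% names(arcs)) {
    arcs[["frequency"]] <- rep(NA_character_, nrow(arcs))
  }
  if (nrow(arcs)) {
    arcs <- arcs[c("source", "target", "frequency")]
    arcs$source <- as.character(arcs$source)
    arcs$target <- as.character(arcs$target)
    arcs$frequency <- as.character(arcs$frequency)
    arcs$frequency[!is.na(arcs$frequency) & !nzchar(arcs$frequency)] <- NA_character_
  } else {
    arcs <- data.frame(source = character(), target = character(),
                       frequency = character(), stringsAsFactors = FALSE)
  }
  organizations <- organizations[order(organizations$org_id), , drop = FALSE]
  rownames(organizations) <- NULL
  if (nrow(arcs)) {
    arcs <- arcs[order(arcs$source, arcs$target), , drop = FALSE]
    rownames(arcs) <- NULL
  }
  net <- structure(list(organizations = organizations, arcs = arcs,
                        subcity_label = as.character(subcity_label)),
                   class = "referral_network")
  validate_network(net, catalogue = catalogue)
  net
}

# normalise a ';'-separated service string: trimmed, sorted, deduplicated
canonical_services <- function(s) {
  vapply(as.character(s), function(si) {
    if (is.na(si) || !nzchar(si)) return("")
    codes <- sort(unique(trimws(strsplit(si, ";", fixed = TRUE)[[1]])))
    paste(codes[nzchar(codes)], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Services provided by each organization
#'
#' @param net A [referral_network()].
#' @return Named list of character vectors of service codes, one per
#'   organization, named by `org_id`.
#' @export
org_services <- function(net) {
  stopifnot(inherits(net, "referral_network"))
  out <- lapply(net$organizations$services, function(s) {
    if (!nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  names(out) <- net$organizations$org_id
  out
}

#' Validate a referral network
#'
#' Checks the structural invariants: unique organization ids, organization
#' type and management drawn from their closed sets, service codes within the
#' catalogue, every arc endpoint present in the node table, no self-loops and
#' no duplicate arcs.
#'
#' @inheritParams org_services
#' @param catalogue [service_catalogue()] defining admissible service codes.
#' @return `net`, invisibly; errors on the first violated invariant.
#' @export
validate_network <- function(net, catalogue = service_catalogue()) {
  stopifnot(inherits(net, "referral_network"))
  orgs <- net$organizations
  arcs <- net$arcs
  if (any(duplicated(orgs$org_id))) {
    stop("duplicate org_id: ",
         paste(unique(orgs$org_id[duplicated(orgs$org_id)]), collapse = ", "))
  }
  bad_type <- setdiff(unique(orgs$org_type), ORG_TYPES)
  if (length(bad_type)) stop("unknown org_type: ", paste(bad_type, collapse = ", "))
  bad_mgmt <- setdiff(unique(orgs$management), MANAGEMENT_TYPES)
  if (length(bad_mgmt)) stop("unknown management: ", paste(bad_mgmt, collapse = ", "))
  if (any(orgs$clients_per_month < 0, na.rm = TRUE) ||
      any(orgs$clinical_staff < 0, na.rm = TRUE) ||
      any(orgs$nonclinical_staff < 0, na.rm = TRUE)) {
    stop("client and staffing counts must be nonnegative")
  }
  known <- catalogue_codes(catalogue)
  svc <- unlist(org_services(net), use.names = FALSE)
  bad_svc <- setdiff(unique(svc), known)
  if (length(bad_svc)) stop("service codes outside catalogue: ",
                            paste(bad_svc, collapse = ", "))
  if (nrow(arcs)) {
    dangling <- setdiff(unique(c(arcs$source, arcs$target)), orgs$org_id)
    if (length(dangling)) stop("dangling endpoint: ", paste(dangling, collapse = ", "))
    if (any(arcs$source == arcs$target)) {
      stop("self-loop arc: ", paste(unique(arcs$source[arcs$source == arcs$target]),
                                    collapse = ", "))
    }
    key <- paste(arcs$source, arcs$target, sep = "\r")
    if (any(duplicated(key))) {
      stop("duplicate arc: ", paste(unique(gsub("\r", " -> ", key[duplicated(key)])),
                                    collapse = ", "))
    }
    bad_freq <- setdiff(unique(arcs$frequency[!is.na(arcs$frequency)]), FREQ_LEVELS)
    if (length(bad_freq)) stop("unknown frequency level: ",
                               paste(bad_freq, collapse = ", "))
  }
  invisible(net)
}

#' Number of organizations and arcs
#' @inheritParams org_services
#' @return Integer count.
#' @export
n_orgs <- function(net) nrow(net$organizations)

#' @rdname n_orgs
#' @export
n_arcs <- function(net) nrow(net$arcs)

#' Binary adjacency matrix
#'
#' @inheritParams org_services
#' @return A square 0/1 matrix with rows and columns ordered by `org_id`;
#'   entry `(i, j)` is 1 iff the arc i -> j exists. The diagonal is zero and
#'   row sums equal out-degrees.
#' @examples
#' net <- make_paper_fixture("kirkos")
#' sum(adjacency(net))  # arc count
#' @export
adjacency <- function(net) {
  stopifnot(inherits(net, "referral_network"))
  ids <- net$organizations$org_id
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(net$arcs)) {
    A[cbind(match(net$arcs$source, ids), match(net$arcs$target, ids))] <- 1L
  }
  A
}

# rebuild a referral_network from an adjacency matrix, keeping attributes
network_from_adjacency <- function(A, organizations, subcity_label = "",
                                   catalogue = service_catalogue()) {
  ids <- organizations$org_id
  idx <- which(A == 1L, arr.ind = TRUE)
  arcs <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                     stringsAsFactors = FALSE)
  referral_network(organizations, arcs, subcity_label, catalogue = catalogue)
}

#' Read a referral network from CSV files
#'
#' @param nodes_path CSV of organizations with the columns documented in
#'   [referral_network()] (coordinates optional).
#' @param edges_path CSV of arcs with columns `source,target` and optional
#'   `frequency`.
#' @param subcity_label Label attached to the network; defaults to the
#'   `subcity` of the first organization.
#' @param catalogue [service_catalogue()] used for validation.
#' @return A validated [referral_network()].
#' @export
read_network <- function(nodes_path, edges_path, subcity_label = NULL,
                         catalogue = service_catalogue()) {
  for (p in c(nodes_path, edges_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  orgs <- utils::read.csv(nodes_path, stringsAsFactors = FALSE,
                          colClasses = c(org_id = "character", name = "character",
                                         subcity = "character",
                                         org_type = "character",
                                         management = "character",
                                         services = "character"))
  arcs <- utils::read.csv(edges_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (is.null(subcity_label)) {
    subcity_label <- if (nrow(orgs)) as.character(orgs$subcity[1]) else ""
  }
  referral_network(orgs, arcs, subcity_label, catalogue = catalogue)
}

#' Write a referral network to CSV files
#'
#' The written files round-trip: [read_network()] on the output reproduces the
#' network field for field, including the optional `frequency` column.
#'
#' @inheritParams org_services
#' @param nodes_path,edges_path Output CSV paths.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, nodes_path, edges_path) {
  stopifnot(inherits(net, "referral_network"))
  utils::write.csv(net$organizations, nodes_path, row.names = FALSE, na = "")
  utils::write.csv(net$arcs, edges_path, row.names = FALSE, na = "")
  invisible(net)
}

#' @export
print.referral_network <- function(x, ...) {
  cat("Referral network", if (nzchar(x$subcity_label)) paste0("'", x$subcity_label, "'"),
      "\n  organizations:", n_orgs(x), "\n  referral arcs:", n_arcs(x), "\n")
  tt <- table(x$organizations$org_type)
  cat("  types: ", paste(names(tt), tt, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot a referral network sociogram
#'
#' Convenience plot via \pkg{igraph} (if installed): nodes coloured by
#' organization type, arrows are client referrals.
#'
#' @param x A [referral_network()].
#' @param ... Passed to `plot.igraph`.
#' @export
plot.referral_network <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting requires the igraph package")
  }
  g <- igraph::graph_from_data_frame(
    x$arcs[c("source", "target")], directed = TRUE,
    vertices = x$organizations[c("org_id", "org_type")])
  pal <- grDevices::hcl.colors(length(ORG_TYPES), "Dark 3")
  col <- pal[match(igraph::V(g)$org_type, ORG_TYPES)]
  igraph::plot.igraph(g, vertex.color = col, edge.arrow.size = 0.4, ...)
  invisible(x)
}
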
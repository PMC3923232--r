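#' Organization directory
#'
#' The first workshop handout: one entry per organization, sorted by id, with
#' the services rendered as catalogue domain labels and a contact
#' placeholder (fixtures carry no real contact information).
#'
#' @param net A [referral_network()].
#' @param catalogue A [service_catalogue()] used to render domain labels.
#' @return Data frame with columns `org_id`, `name`, `org_type`,
#'   `services_offered`, `contact`.
#' @examples
#' head(directory(make_paper_fixture("kirkos")))
#' @export
directory <- function(net, catalogue = service_catalogue()) {
  stopifnot(inherits(net, "referral_network"))
  svc <- org_services(net)
  domains <- vapply(svc, function(s) {
    labs <- names(catalogue)[vapply(catalogue, function(codes)
      length(intersect(s, codes)) > 0L, logical(1))]
    paste(labs, collapse = ";")
  }, character(1))
  orgs <- net$organizations
  out <- data.frame(org_id = orgs$org_id, name = orgs$name,
                    org_type = orgs$org_type,
                    services_offered = unname(domains[orgs$org_id]),
                    contact = paste0("contact@", tolower(orgs$org_id),
                                     ".example"),
                    stringsAsFactors = FALSE)
  out[order(out$org_id), , drop = FALSE]
}

#' Complementary-service table
#'
#' The second workshop handout: for each organization, every other
#' organization offering at least one service code the organization itself
#' lacks — the in-network candidates for new referral links.
#'
#' @inheritParams directory
#' @return Named list mapping each `org_id` to a sorted character vector of
#'   complementary `org_id`s (empty for organizations offering the full
#'   catalogue).
#' @export
complementary_table <- function(net, catalogue = service_catalogue()) {
  stopifnot(inherits(net, "referral_network"))
  svc <- org_services(net)
  ids <- net$organizations$org_id
  all_codes <- catalogue_codes(catalogue)
  out <- lapply(ids, function(i) {
    lacking <- setdiff(all_codes, svc[[i]])
    if (!length(lacking)) return(character())
    sort(ids[ids != i & vapply(ids, function(j)
      length(intersect(svc[[j]], lacking)) > 0L, logical(1))])
  })
  names(out) <- ids
  out
}

#' Export a sociogram file
#'
#' Serialises the network for downstream drawing tools: GraphViz DOT or
#' GraphML. Node attributes `org_type` and `services` and all directed edges
#' are written; no layout or aesthetics. GraphML output re-imports with
#' [import_sociogram()] (or any GraphML reader) with node and edge sets, and
#' hence the mixing matrix, preserved exactly.
#'
#' @inheritParams directory
#' @param path Output file path.
#' @param format `"graphml"` (default) or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_sociogram <- function(net, path, format = c("graphml", "dot")) {
  stopifnot(inherits(net, "referral_network"))
  format <- match.arg(format)
  orgs <- net$organizations
  arcs <- net$arcs
  xml_escape <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  lines <- if (format == "dot") {
    c("digraph referrals {",
      sprintf("  \"%s\" [org_type=\"%s\", services=\"%s\"];",
              orgs$org_id, orgs$org_type, orgs$services),
      if (nrow(arcs)) sprintf("  \"%s\" -> \"%s\";", arcs$source, arcs$target),
      "}")
  } else {
    c('<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="d0" for="node" attr.name="org_type" attr.type="string"/>',
      '  <key id="d1" for="node" attr.name="services" attr.type="string"/>',
      '  <graph id="G" edgedefault="directed">',
      sprintf(paste0('    <node id="%s"><data key="d0">%s</data>',
                     '<data key="d1">%s</data></node>'),
              xml_escape(orgs$org_id), xml_escape(orgs$org_type),
              xml_escape(orgs$services)),
      if (nrow(arcs)) sprintf('    <edge source="%s" target="%s"/>',
                              xml_escape(arcs$source), xml_escape(arcs$target)),
      '  </graph>',
      '</graphml>')
  }
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop("cannot write to ", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Import a GraphML sociogram
#'
#' Reads node ids, the `org_type` and `services` node attributes, and the
#' directed edge list back from a GraphML file written by
#' [export_sociogram()]. Attributes not represented in GraphML (staffing,
#' client volumes, coordinates) are filled with placeholders, so the import
#' is a structural — not field-for-field — inverse; node and edge sets and
#' every arc's endpoints are preserved.
#'
#' @param path GraphML file.
#' @param subcity_label Label for the reconstructed network.
#' @return A [referral_network()].
#' @export
import_sociogram <- function(path, subcity_label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node, sprintf(".//g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) "" else xml2::xml_text(d)
  }
  orgs <- data.frame(
    org_id = xml2::xml_attr(nodes, "id"),
    name = xml2::xml_attr(nodes, "id"),
    subcity = subcity_label,
    org_type = vapply(nodes, get_data, character(1), key = "d0"),
    management = "other",
    services = vapply(nodes, get_data, character(1), key = "d1"),
    clients_per_month = 0L, clinical_staff = 0L, nonclinical_staff = 0L,
    x = NA_real_, y = NA_real_, stringsAsFactors = FALSE)
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  arcs <- data.frame(source = xml2::xml_attr(edges, "source"),
                     target = xml2::xml_attr(edges, "target"),
                     stringsAsFactors = FALSE)
  referral_network(orgs, arcs, subcity_label)
}
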
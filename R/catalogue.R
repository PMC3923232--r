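#' Service catalogue
#'
#' A service catalogue maps service *domains* (e.g. family planning, HIV care)
#' to sets of service codes. Gap detection and the complementary-service table
#' are defined relative to a catalogue. The default distinguishes one family
#' planning code from four HIV service codes, so that both whole-domain and
#' partial-coverage gaps are expressible.
#'
#' @param domains Named list of character vectors; names are domain labels,
#'   elements are service codes. Codes must be unique across domains.
#' @return An object of class `service_catalogue` (a named list of character
#'   vectors).
#' @examples
#' cat <- service_catalogue()
#' names(cat)
#' @export
service_catalogue <- function(domains = list(
  FP  = "fp",
  HIV = c("hiv_testing", "hiv_art", "hiv_care_support", "hiv_pmtct")
)) {
  if (!is.list(domains) || length(domains) == 0L || is.null(names(domains)) ||
      any(!nzchar(names(domains)))) {
    stop("`domains` must be a nonempty named list of character vectors")
  }
  domains <- lapply(domains, as.character)
  codes <- unlist(domains, use.names = FALSE)
  if (any(duplicated(codes))) {
    stop("service codes must be unique across domains: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  structure(domains, class = "service_catalogue")
}

catalogue_codes <- function(catalogue) {
  unlist(unclass(catalogue), use.names = FALSE)
}

#' @export
print.service_catalogue <- function(x, ...) {
  cat("Service catalogue:", length(x), "domains\n")
  for (d in names(x)) cat("  ", d, ": ", paste(x[[d]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
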
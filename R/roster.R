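#' Snowball closure of a nomination census
#'
#' Starting from seed organizations (e.g. those known to the national HIV
#' office), the candidate pool is every organization reachable through chains
#' of nominations: seeds name organizations, the newly named organizations are
#' asked in turn, until no new names arise.
#'
#' @param seeds Character vector of seed `org_id`s (nonempty).
#' @param nominations Data frame with columns `nominator`, `nominee`; one row
#'   per "A named B" datum. Self-nominations are rejected.
#' @return Character vector of reachable `org_id`s (sorted; includes seeds).
#'   Deterministic and independent of row order.
#' @examples
#' noms <- data.frame(nominator = c("A", "B"), nominee = c("B", "C"))
#' snowball_closure("A", noms)
#' @export
snowball_closure <- function(seeds, nominations) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("seed set must be nonempty")
  nominations <- check_nominations(nominations)
  reached <- seeds
  frontier <- seeds
  while (length(frontier)) {
    nxt <- unique(nominations$nominee[nominations$nominator %in% frontier])
    frontier <- setdiff(nxt, reached)
    reached <- c(reached, frontier)
  }
  sort(reached)
}

check_nominations <- function(nominations) {
  nominations <- as.data.frame(nominations, stringsAsFactors = FALSE)
  if (nrow(nominations) == 0L) {
    return(data.frame(nominator = character(), nominee = character(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("nominator", "nominee") %in% names(nominations)))
  nominations$nominator <- as.character(nominations$nominator)
  nominations$nominee <- as.character(nominations$nominee)
  if (any(nominations$nominator == nominations$nominee)) {
    stop("self-nomination: ",
         paste(unique(nominations$nominator[
           nominations$nominator == nominations$nominee]), collapse = ", "))
  }
  nominations
}

#' Roster inclusion rule
#'
#' An organization from the candidate pool enters the analyzable roster when
#' it was named by at least two *distinct* other organizations. Private
#' clinics — seldom named by organizations serving low-income clients — are
#' admitted with a single nomination. Seed organizations are always retained:
#' they anchor the census. Repeated nominations from the same nominator count
#' once.
#'
#' @param candidates Character vector of candidate `org_id`s (typically from
#'   [snowball_closure()]).
#' @param nominations Data frame `nominator,nominee`.
#' @param is_private_clinic Predicate: function taking an `org_id`, returning
#'   `TRUE` for private clinics; or a character vector of private-clinic ids.
#' @param seeds Character vector of always-retained seed ids (default none).
#' @return Sorted character vector of included `org_id`s, a subset of
#'   `candidates`.
#' @examples
#' noms <- data.frame(nominator = c("A", "B", "A"), nominee = c("C", "C", "D"))
#' apply_inclusion_rule(c("A", "B", "C", "D"), noms,
#'                      is_private_clinic = "D", seeds = c("A", "B"))
#' @export
apply_inclusion_rule <- function(candidates, nominations, is_private_clinic,
                                 seeds = character()) {
  candidates <- unique(as.character(candidates))
  nominations <- check_nominations(nominations)
  if (is.character(is_private_clinic)) {
    private_ids <- is_private_clinic
    is_private_clinic <- function(id) id %in% private_ids
  }
  stopifnot(is.function(is_private_clinic))
  nominations <- unique(nominations[c("nominator", "nominee")])
  n_nominators <- table(factor(nominations$nominee, levels = candidates))
  keep <- vapply(candidates, function(id) {
    k <- n_nominators[[id]]
    (id %in% seeds) || k >= 2L || (isTRUE(is_private_clinic(id)) && k >= 1L)
  }, logical(1))
  sort(candidates[keep])
}

#' Build the analyzable roster from nomination data
#'
#' Convenience wrapper chaining [snowball_closure()] and
#' [apply_inclusion_rule()].
#'
#' @inheritParams snowball_closure
#' @inheritParams apply_inclusion_rule
#' @return Sorted character vector of included `org_id`s.
#' @export
build_roster <- function(seeds, nominations, is_private_clinic) {
  candidates <- snowball_closure(seeds, nominations)
  nominations <- check_nominations(nominations)
  nominations <- nominations[nominations$nominator %in% candidates &
                               nominations$nominee %in% candidates, , drop = FALSE]
  apply_inclusion_rule(candidates, nominations, is_private_clinic, seeds = seeds)
}

#' Read nomination records from CSV
#'
#' @param path CSV with header `nominator,nominee`.
#' @return Data frame of nomination records.
#' @export
read_nominations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_nominations(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = "character"))
}
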
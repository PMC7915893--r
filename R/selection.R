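# Downstream selection logic of the first database search: restrict
# identifications to plasma-membrane proteins, rank by posterior error
# probability (PEP, smaller = more confident), keep the top N per
# fractionation method, and intersect methods for common signatures.

#' Read a protein identification table
#'
#' @param path TSV with columns `accession`, `gene` (optional), `pep`,
#'   `method`, `n_psms` (optional).
#' @return A data frame of identifications.
#' @export
read_identifications <- function(path) {
  ids <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("accession", "pep", "method")
  missing <- setdiff(required, names(ids))
  if (length(missing))
    stop("identification table lacks column(s): ",
         paste(missing, collapse = ", "))
  validate_identifications(ids)
  ids
}

validate_identifications <- function(ids) {
  if (any(!nzchar(ids$accession)))
    stop("empty accession in identification table")
  if (any(ids$pep < 0 | ids$pep > 1, na.rm = TRUE))
    stop("PEP scores must lie in [0, 1]")
  invisible(ids)
}

#' Read a membrane registry
#'
#' @param path Text file, one plasma-membrane accession per line.
#' @return Character vector of accessions.
#' @export
read_membrane_registry <- function(path) {
  acc <- readLines(path)
  acc <- trimws(acc)
  acc[nzchar(acc)]
}

strip_isoform <- function(accession) sub("-\\d+$", "", accession)

#' Filter identifications to a membrane registry
#'
#' Keeps exactly the records whose accession is in the registry (order
#' preserved). Isoform suffixes ("-2") are stripped before comparison by
#' default, since GO-derived registries are keyed by canonical accessions.
#'
#' @param ids Identification data frame (see [read_identifications()]).
#' @param registry Character vector of membrane accessions.
#' @param collapse_isoforms Strip `-N` isoform suffixes before matching.
#' @return The filtered data frame.
#' @export
filter_membrane <- function(ids, registry, collapse_isoforms = TRUE) {
  if (length(registry) == 0L)
    stop("membrane registry is empty; cannot filter")
  key <- if (collapse_isoforms) strip_isoform(ids$accession) else ids$accession
  reg <- if (collapse_isoforms) strip_isoform(registry) else registry
  ids[key %in% reg, , drop = FALSE]
}

#' Rank identifications by PEP and keep the top n
#'
#' Sorts ascending by PEP (smaller is better), breaking ties by descending
#' `n_psms` then ascending accession, and returns the first `min(n, nrow)`
#' records. Duplicate accessions are collapsed to their best-PEP record
#' first, so the result is one row per protein.
#'
#' @param ids Identification data frame.
#' @param n Number of proteins to keep (default 250, the high-confidence cut
#'   used per fractionation method).
#' @return Ranked data frame with a `rank` column.
#' @export
top_by_pep <- function(ids, n = 250L) {
  if (length(n) != 1L || n < 1)
    stop("n must be >= 1")
  validate_identifications(ids)
  if (!"n_psms" %in% names(ids)) ids$n_psms <- NA_integer_
  psms <- ifelse(is.na(ids$n_psms), -Inf, ids$n_psms)
  ord <- order(ids$pep, -psms, ids$accession)
  ids <- ids[ord, , drop = FALSE]
  ids <- ids[!duplicated(ids$accession), , drop = FALSE]
  ids <- utils::head(ids, n)
  ids$rank <- seq_len(nrow(ids))
  rownames(ids) <- NULL
  ids
}

#' Intersect two ranked identification lists
#'
#' Returns the accessions present in both lists, ordered by the better
#' (smaller) of the two PEP ranks, ties broken by accession.
#'
#' @param list_a,list_b Ranked data frames from [top_by_pep()] (one row per
#'   accession; a `rank` column is added if absent).
#' @return Data frame with columns `accession`, `rank_a`, `rank_b`,
#'   `best_rank`.
#' @export
intersect_methods <- function(list_a, list_b) {
  for (nm in c("a", "b")) {
    l <- if (nm == "a") list_a else list_b
    if (anyDuplicated(l$accession))
      stop("duplicate accessions in list ", nm,
           "; deduplicate with top_by_pep() first")
  }
  if (!"rank" %in% names(list_a)) list_a$rank <- seq_len(nrow(list_a))
  if (!"rank" %in% names(list_b)) list_b$rank <- seq_len(nrow(list_b))
  common <- intersect(list_a$accession, list_b$accession)
  out <- data.frame(
    accession = common,
    rank_a = list_a$rank[match(common, list_a$accession)],
    rank_b = list_b$rank[match(common, list_b$accession)],
    stringsAsFactors = FALSE
  )
  out$best_rank <- pmin(out$rank_a, out$rank_b)
  out <- out[order(out$best_rank, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full selection pipeline
#'
#' Fixed order: membrane filter, then PEP ranking with top-N per method,
#' then cross-method intersection.
#'
#' @param ids Identification data frame covering both methods.
#' @param registry Membrane accession vector.
#' @param methods Two method tags to compare (default `c("RPS", "SCX")`).
#' @param top_n Top-N cut per method (default 250).
#' @inheritParams filter_membrane
#' @return As [intersect_methods()].
#' @export
select_common_proteins <- function(ids, registry, methods = c("RPS", "SCX"),
                                   top_n = 250L, collapse_isoforms = TRUE) {
  stopifnot(length(methods) == 2L)
  kept <- filter_membrane(ids, registry, collapse_isoforms)
  ranked <- lapply(methods, function(m)
    top_by_pep(kept[kept$method == m, , drop = FALSE], top_n))
  intersect_methods(ranked[[1L]], ranked[[2L]])
}
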
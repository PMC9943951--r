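#' Participant-level quality checks
#'
#' `check_vigilance()` passes iff all vigilance items were sorted into a
#' single cluster of their own — the duplicated synthetic clip must be
#' spotted and isolated, with no test item sharing its cluster.
#' `check_single_cluster()` fails iff all test items were lumped into one
#' cluster, a response pattern anomalous enough in sorting tasks to warrant
#' exclusion. Both are deterministic predicates of the partition shape.
#'
#' @param response a [sorting_response()].
#' @param manifest a [generate_manifest()] manifest; for the vigilance check
#'   it must contain at least 2 vigilance items.
#' @return logical: `TRUE` = pass.
#' @export
check_vigilance <- function(response, manifest) {
  stop_if_invalid(response, manifest)
  vig <- vigilance_items(manifest)$item_id
  if (length(vig) < 2)
    stop("vigilance check inapplicable: manifest has fewer than 2 vigilance items")
  vc <- unique(response$assignment[vig])
  if (length(vc) != 1) return(FALSE)
  !vc %in% response$assignment[test_items(manifest)$item_id]
}

#' @rdname check_vigilance
#' @export
check_single_cluster <- function(response, manifest) {
  count_clusters(response, manifest) > 1
}

#' Apply the participant exclusion rules
#'
#' Applies the four exclusion rules in fixed order — failed vigilance check,
#' prior familiarity with the talkers (debrief flag), insufficient exposure
#' (debrief flag: watched less than one season), single-cluster anomaly — and
#' attributes each participant to the first matching rule. Because the rules
#' are independent predicates, order affects only ledger attribution, never
#' the retained set.
#'
#' @param responses list of [sorting_response()] objects.
#' @param metadata data frame with columns `participant_id`,
#'   `prior_familiarity`, `insufficient_exposure` (logical); every participant
#'   must be present — missing metadata is an error, never silent retention.
#' @param manifest a [generate_manifest()] manifest.
#' @return A list of class `qc_result`:
#'   `retained` (list of responses), `ledger` (data frame
#'   `participant_id,outcome`), `counts` (named integer vector over the five
#'   outcomes).
#' @examples
#' cohort <- simulate_cohort(cohort_config(
#'   group_sizes = c(THI_AHI = 5, THI_ALO = 5, TLO_AHI = 5, TLO_ALO = 5),
#'   seed = 1, planted = c(vigilance_fail = 2)))
#' qc <- apply_exclusions(cohort$responses, cohort$metadata, cohort$manifest)
#' qc$counts
#' @export
apply_exclusions <- function(responses, metadata, manifest) {
  ids <- vapply(responses, function(r) r$participant_id, character(1))
  miss <- setdiff(ids, metadata$participant_id)
  if (length(miss))
    stop("metadata missing for participant(s): ", paste(miss, collapse = ", "))
  meta <- metadata[match(ids, metadata$participant_id), , drop = FALSE]
  outcome <- vapply(seq_along(responses), function(i) {
    r <- responses[[i]]
    if (!check_vigilance(r, manifest)) return("vigilance_fail")
    if (isTRUE(meta$prior_familiarity[i])) return("prior_familiarity")
    if (isTRUE(meta$insufficient_exposure[i])) return("insufficient_exposure")
    if (!check_single_cluster(r, manifest)) return("single_cluster_anomaly")
    "retained"
  }, character(1))
  lv <- c("retained", "vigilance_fail", "prior_familiarity",
          "insufficient_exposure", "single_cluster_anomaly")
  structure(list(
    retained = responses[outcome == "retained"],
    ledger = data.frame(participant_id = ids, outcome = outcome,
                        stringsAsFactors = FALSE),
    counts = stats::setNames(
      as.integer(table(factor(outcome, levels = lv))), lv)
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  n <- nrow(x$ledger)
  cat(sprintf("Participant QC: %d in, %d retained, %d excluded\n",
              n, x$counts[["retained"]], n - x$counts[["retained"]]))
  excl <- x$counts[setdiff(names(x$counts), "retained")]
  for (nm in names(excl))
    if (excl[[nm]] > 0) cat(sprintf("  %-22s %d\n", nm, excl[[nm]]))
  invisible(x)
}

#' Write the exclusion ledger and summary
#'
#' @param qc a [apply_exclusions()] result.
#' @param path CSV path for the ledger (`participant_id,outcome`).
#' @export
write_ledger <- function(qc, path) {
  utils::write.csv(qc$ledger, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
write_qc_summary <- function(qc, path) {
  jsonlite::write_json(as.list(qc$counts), path, auto_unbox = TRUE)
  invisible(path)
}
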
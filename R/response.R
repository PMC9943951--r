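#' Construct a single participant's sorting response
#'
#' A response is the participant's partition of the manifest items: a total
#' mapping from `item_id` to an arbitrary cluster label. Cluster labels are
#' opaque and unordered — participants circled unlabeled clusters — so two
#' responses are equivalent iff they induce the same partition (see
#' [same_partition()]). Group membership (talker/accent familiarity) is carried
#' on the response because it was fixed at recruitment, not inferred from
#' behaviour.
#'
#' @param participant_id unique participant token.
#' @param assignment named character vector: names are `item_id`s, values are
#'   cluster labels.
#' @param talker_familiarity `"HI"` or `"LO"`.
#' @param accent_familiarity `"HI"` or `"LO"`.
#' @return An object of class `sorting_response`.
#' @examples
#' m <- generate_manifest(2, 2, 0)
#' r <- sorting_response("P1",
#'   c(T1_01 = "a", T1_02 = "a", T2_01 = "b", T2_02 = "b"))
#' score_response(r, m)
#' @export
sorting_response <- function(participant_id, assignment,
                             talker_familiarity = "HI",
                             accent_familiarity = "HI") {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("`assignment` must be a named vector (names = item_id)")
  talker_familiarity <- match.arg(talker_familiarity, c("HI", "LO"))
  accent_familiarity <- match.arg(accent_familiarity, c("HI", "LO"))
  structure(list(
    participant_id = as.character(participant_id),
    talker_familiarity = talker_familiarity,
    accent_familiarity = accent_familiarity,
    assignment = stats::setNames(as.character(assignment), names(assignment))
  ), class = "sorting_response")
}

#' @export
print.sorting_response <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat(sprintf("Sorting response %s [Talker%s/Accent%s]: %d items in %d clusters\n",
              x$participant_id, x$talker_familiarity, x$accent_familiarity,
              length(x$assignment), k))
  invisible(x)
}

#' Group label of a response or score row
#'
#' Combines the two familiarity factors into the conventional group code,
#' e.g. `"THI_AHI"` for listeners familiar with both the talkers and the
#' accent.
#'
#' @param talker_familiarity,accent_familiarity `"HI"`/`"LO"` vectors.
#' @return character vector of group codes.
#' @export
group_code <- function(talker_familiarity, accent_familiarity) {
  paste0("T", talker_familiarity, "_A", accent_familiarity)
}

#' Validate a response against a manifest
#'
#' A response is valid iff its assignment is a total function on the manifest
#' items: every manifest `item_id` appears exactly once and no unknown ids
#' appear. The report names every offending id; callers decide whether to
#' stop.
#'
#' @param response a [sorting_response()].
#' @param manifest a [generate_manifest()] manifest.
#' @return A list of class `validation_report` with elements `valid`,
#'   `missing_items`, `duplicate_items`, `unknown_items`.
#' @export
validate_response <- function(response, manifest) {
  ids <- names(response$assignment)
  missing <- setdiff(manifest$item_id, ids)
  unknown <- setdiff(ids, manifest$item_id)
  dup <- unique(ids[duplicated(ids)])
  structure(list(
    participant_id = response$participant_id,
    valid = length(missing) == 0 && length(unknown) == 0 && length(dup) == 0,
    missing_items = missing,
    duplicate_items = dup,
    unknown_items = unknown
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Response %s: %s\n", x$participant_id,
              if (x$valid) "valid" else "INVALID"))
  if (length(x$missing_items))
    cat("  missing items:   ", paste(x$missing_items, collapse = ", "), "\n")
  if (length(x$duplicate_items))
    cat("  duplicate items: ", paste(x$duplicate_items, collapse = ", "), "\n")
  if (length(x$unknown_items))
    cat("  unknown items:   ", paste(x$unknown_items, collapse = ", "), "\n")
  invisible(x)
}

stop_if_invalid <- function(response, manifest) {
  rep <- validate_response(response, manifest)
  if (!rep$valid) {
    msg <- utils::capture.output(print(rep))
    stop("invalid sorting response:\n", paste(msg, collapse = "\n"), call. = FALSE)
  }
  invisible(rep)
}

#' Label-invariant partition equality
#'
#' Two responses are equal iff they induce the same partition of the same item
#' set, regardless of the arbitrary cluster labels.
#'
#' @param a,b [sorting_response()] objects (or named cluster vectors).
#' @return logical.
#' @export
same_partition <- function(a, b) {
  xa <- if (inherits(a, "sorting_response")) a$assignment else a
  xb <- if (inherits(b, "sorting_response")) b$assignment else b
  if (length(xa) != length(xb)) return(FALSE)
  if (!setequal(names(xa), names(xb))) return(FALSE)
  xb <- xb[names(xa)]
  canon <- function(x) as.integer(factor(x, levels = unique(x)))
  identical(canon(unname(xa)), canon(unname(xb)))
}

#' Read and write sorting responses and participant metadata
#'
#' Responses use a long CSV with one row per (participant, item):
#' `participant_id,talker_familiarity,accent_familiarity,item_id,cluster_label`.
#' Metadata is a per-participant CSV
#' `participant_id,prior_familiarity,insufficient_exposure` with 0/1 flags
#' taken from the debrief questionnaire. Writing then reading round-trips to
#' equal objects.
#'
#' @param path file path.
#' @return `read_responses()` returns a list of [sorting_response()] objects;
#'   `read_metadata()` a data frame with logical flag columns.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("participant_id", "talker_familiarity", "accent_familiarity",
            "item_id", "cluster_label")
  if (!all(need %in% names(df)))
    stop("response CSV must have columns ", paste(need, collapse = ", "))
  ids <- unique(df$participant_id)
  lapply(ids, function(p) {
    rows <- df[df$participant_id == p, , drop = FALSE]
    sorting_response(
      participant_id = p,
      assignment = stats::setNames(rows$cluster_label, rows$item_id),
      talker_familiarity = rows$talker_familiarity[1],
      accent_familiarity = rows$accent_familiarity[1]
    )
  })
}

#' @rdname read_responses
#' @param responses list of [sorting_response()] objects.
#' @export
write_responses <- function(responses, path) {
  rows <- do.call(rbind, lapply(responses, function(r) {
    data.frame(participant_id = r$participant_id,
               talker_familiarity = r$talker_familiarity,
               accent_familiarity = r$accent_familiarity,
               item_id = names(r$assignment),
               cluster_label = unname(r$assignment),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_responses
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("participant_id", "prior_familiarity", "insufficient_exposure")
  if (!all(need %in% names(df)))
    stop("metadata CSV must have columns ", paste(need, collapse = ", "))
  df <- df[need]
  df$prior_familiarity <- df$prior_familiarity %in% c("1", "TRUE", "true")
  df$insufficient_exposure <- df$insufficient_exposure %in% c("1", "TRUE", "true")
  df
}

#' @rdname read_responses
#' @param metadata metadata data frame.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  out$prior_familiarity <- as.integer(out$prior_familiarity)
  out$insufficient_exposure <- as.integer(out$insufficient_exposure)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
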
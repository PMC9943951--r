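#' Build the pairwise co-clustering response matrix
#'
#' The response matrix encodes one participant's sort as a symmetric binary
#' matrix over the test items: entry (i, j) is 1 iff items i and j were placed
#' in the same cluster. Vigilance items are removed before the matrix is
#' built — they belong to the attention check, not to performance scoring. The
#' diagonal is trivially 1 and is never included in any score ("unique pairs"
#' only).
#'
#' @param response a [sorting_response()], valid against `manifest`.
#' @param manifest a [generate_manifest()] manifest.
#' @return A 0/1 matrix of class `response_matrix`, rows and columns named and
#'   ordered by the manifest's test items, with the test-talker labels in
#'   attribute `"talker_id"`.
#' @export
build_response_matrix <- function(response, manifest) {
  stop_if_invalid(response, manifest)
  test <- test_items(manifest)
  cl <- response$assignment[test$item_id]
  m <- 1L * outer(cl, cl, "==")
  dimnames(m) <- list(test$item_id, test$item_id)
  attr(m, "talker_id") <- stats::setNames(test$talker_id, test$item_id)
  class(m) <- c("response_matrix", class(m))
  m
}

talkers_of <- function(m, manifest = NULL) {
  tk <- attr(m, "talker_id")
  if (is.null(tk)) {
    if (is.null(manifest)) stop("manifest needed to recover talker labels")
    test <- test_items(manifest)
    tk <- stats::setNames(test$talker_id, test$item_id)[rownames(m)]
  }
  tk
}

#' Per-participant sorting scores
#'
#' Three dependent measures summarise one participant's sort of the test
#' items:
#'
#' * `count_clusters()` — the number of clusters containing at least one test
#'   item, i.e. the number of perceived talkers (2 is veridical in the default
#'   design). Clusters holding only vigilance items do not count.
#' * `telling_together()` — the mean of the response-matrix entries over all
#'   unique pairs of items truly produced by the same talker. 1 means every
#'   same-talker pair was co-clustered (perfect); splitting a talker across
#'   clusters pulls the score toward 0.
#' * `telling_apart()` — the mean over all unique pairs of items from
#'   different talkers. 0 means talkers were never mixed within a cluster
#'   (perfect); it is an error rate that grows toward 1 as talkers are merged.
#'
#' With more than two talkers, `telling_apart()` averages over all
#' cross-talker pairs, a natural generalisation of the two-talker definition.
#'
#' `score_response()` computes all three from a single matrix build and
#' returns a `score_set`.
#'
#' @param response a [sorting_response()].
#' @param manifest a [generate_manifest()] manifest.
#' @param matrix a [build_response_matrix()] result.
#' @return `count_clusters()` an integer; the two scores fractions in
#'   \[0, 1\]; `score_response()` a list of class `score_set` with elements
#'   `n_clusters`, `telling_together`, `telling_apart`.
#' @examples
#' m <- generate_manifest()
#' truth <- ground_truth_response(m)
#' unlist(score_response(truth, m))  # 2, 1, 0
#' @export
count_clusters <- function(response, manifest) {
  stop_if_invalid(response, manifest)
  cl <- response$assignment[test_items(manifest)$item_id]
  length(unique(cl))
}

#' @rdname count_clusters
#' @export
telling_together <- function(matrix, manifest = NULL) {
  tk <- talkers_of(matrix, manifest)
  within <- outer(tk, tk, "==") & upper.tri(matrix)
  if (!any(within))
    stop("telling-together undefined: no talker contributes two or more test items")
  mean(matrix[within])
}

#' @rdname count_clusters
#' @export
telling_apart <- function(matrix, manifest = NULL) {
  tk <- talkers_of(matrix, manifest)
  if (length(unique(tk)) < 2)
    stop("telling-apart undefined: fewer than two test talkers")
  between <- outer(tk, tk, "!=") & upper.tri(matrix)
  mean(matrix[between])
}

#' @rdname count_clusters
#' @export
score_response <- function(response, manifest) {
  m <- build_response_matrix(response, manifest)
  structure(list(
    n_clusters = count_clusters(response, manifest),
    telling_together = telling_together(m),
    telling_apart = telling_apart(m)
  ), class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("clusters: %d  telling-together: %.3f  telling-apart: %.3f\n",
              x$n_clusters, x$telling_together, x$telling_apart))
  invisible(x)
}

#' The veridical sort of a manifest
#'
#' One cluster per test talker plus, when present, an isolated vigilance
#' cluster: the response an ideal participant would give. Scores to
#' `(n_talkers, 1, 0)`.
#'
#' @param manifest a [generate_manifest()] manifest.
#' @param participant_id,talker_familiarity,accent_familiarity passed to
#'   [sorting_response()].
#' @return a [sorting_response()].
#' @export
ground_truth_response <- function(manifest, participant_id = "ideal",
                                  talker_familiarity = "HI",
                                  accent_familiarity = "HI") {
  lab <- ifelse(manifest$is_vigilance, "vig", manifest$talker_id)
  sorting_response(participant_id,
                   stats::setNames(lab, manifest$item_id),
                   talker_familiarity, accent_familiarity)
}

#' Score every response in a cohort
#'
#' @param responses list of [sorting_response()] objects.
#' @param manifest a [generate_manifest()] manifest.
#' @return data frame with one row per participant: `participant_id`,
#'   `talker_familiarity`, `accent_familiarity`, `n_clusters`,
#'   `telling_together`, `telling_apart`.
#' @export
score_cohort <- function(responses, manifest) {
  rows <- lapply(responses, function(r) {
    s <- score_response(r, manifest)
    data.frame(participant_id = r$participant_id,
               talker_familiarity = r$talker_familiarity,
               accent_familiarity = r$accent_familiarity,
               n_clusters = s$n_clusters,
               telling_together = s$telling_together,
               telling_apart = s$telling_apart,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export scores or a response matrix as CSV
#'
#' Floating-point columns are written with 6 decimal places so repeated runs
#' diff cleanly.
#'
#' @param scores a [score_cohort()] data frame.
#' @param path file path.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  for (v in c("telling_together", "telling_apart"))
    out[[v]] <- formatC(out[[v]], format = "f", digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @param matrix a [build_response_matrix()] or [mean_cooccurrence()] matrix.
#' @export
write_matrix <- function(matrix, path) {
  out <- as.data.frame(unclass(matrix))
  if (is.double(matrix))
    out[] <- lapply(out, function(x) formatC(x, format = "f", digits = 6))
  out <- cbind(item_id = rownames(matrix), out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
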
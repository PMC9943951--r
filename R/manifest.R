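#' Build a stimulus manifest
#'
#' A manifest lists the stimuli of one sorting task: each item carries an
#' identifier, the true talker identity, and a flag marking vigilance (catch)
#' items. The default arguments reproduce the canonical two-talker design:
#' 15 naturally varying recordings per talker plus one synthetic vigilance
#' clip presented twice, i.e. 32 items of which 30 are test items.
#'
#' Vigilance items share a dedicated `talker_id` (`"synthetic"`) distinct from
#' every test talker; they are excluded from scoring and exist only for the
#' attention check.
#'
#' @param n_per_talker number of recordings per test talker (>= 2).
#' @param n_talkers number of test talkers (>= 2).
#' @param n_vigilance number of vigilance items (0 disables the check).
#' @return A data frame of class `voice_manifest` with columns `item_id`,
#'   `talker_id` and `is_vigilance`.
#' @examples
#' m <- generate_manifest()
#' nrow(m)              # 32
#' sum(!m$is_vigilance) # 30 test items
#' @export
generate_manifest <- function(n_per_talker = 15, n_talkers = 2, n_vigilance = 2) {
  if (n_per_talker < 2) stop("`n_per_talker` must be >= 2")
  if (n_talkers < 2) stop("`n_talkers` must be >= 2")
  if (n_vigilance < 0) stop("`n_vigilance` must be >= 0")
  talkers <- sprintf("talker%d", seq_len(n_talkers))
  items <- data.frame(
    item_id = as.vector(vapply(seq_len(n_talkers), function(t) {
      sprintf("T%d_%02d", t, seq_len(n_per_talker))
    }, character(n_per_talker))),
    talker_id = rep(talkers, each = n_per_talker),
    is_vigilance = FALSE,
    stringsAsFactors = FALSE
  )
  if (n_vigilance > 0) {
    items <- rbind(items, data.frame(
      item_id = sprintf("VIG_%d", seq_len(n_vigilance)),
      talker_id = "synthetic",
      is_vigilance = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  as_voice_manifest(items)
}

as_voice_manifest <- function(df) {
  stopifnot(all(c("item_id", "talker_id", "is_vigilance") %in% names(df)))
  df$item_id <- as.character(df$item_id)
  df$talker_id <- as.character(df$talker_id)
  df$is_vigilance <- as.logical(df$is_vigilance)
  if (anyDuplicated(df$item_id))
    stop("manifest item_id values must be unique; duplicated: ",
         paste(unique(df$item_id[duplicated(df$item_id)]), collapse = ", "))
  vig_talkers <- unique(df$talker_id[df$is_vigilance])
  test_talkers <- unique(df$talker_id[!df$is_vigilance])
  if (length(intersect(vig_talkers, test_talkers)))
    stop("vigilance items must use a talker_id distinct from all test talkers")
  rownames(df) <- NULL
  class(df) <- c("voice_manifest", "data.frame")
  df
}

#' @export
print.voice_manifest <- function(x, ...) {
  nt <- length(unique(x$talker_id[!x$is_vigilance]))
  cat(sprintf("Stimulus manifest: %d items (%d test items, %d talkers, %d vigilance)\n",
              nrow(x), sum(!x$is_vigilance), nt, sum(x$is_vigilance)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

test_items <- function(manifest) manifest[!manifest$is_vigilance, , drop = FALSE]
vigilance_items <- function(manifest) manifest[manifest$is_vigilance, , drop = FALSE]

#' Read or write a stimulus manifest CSV
#'
#' The manifest dialect is a headed UTF-8 CSV with columns
#' `item_id,talker_id,is_vigilance` (`is_vigilance` coded 0/1). Reading then
#' writing (or vice versa) round-trips exactly.
#'
#' @param path file path.
#' @return `read_manifest()` returns a `voice_manifest`;
#'   `write_manifest()` invisibly returns `path`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("item_id", "talker_id", "is_vigilance")
  if (!all(need %in% names(df)))
    stop("manifest CSV must have columns ", paste(need, collapse = ", "))
  df$is_vigilance <- df$is_vigilance %in% c("1", "TRUE", "true")
  as_voice_manifest(df[need])
}

#' @rdname read_manifest
#' @param manifest a `voice_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  out <- as.data.frame(manifest)
  out$is_vigilance <- as.integer(out$is_vigilance)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
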
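# Independent oracles and small fixture builders used across the suite.

# All set partitions of seq_len(n), as restricted growth strings
# (block label of item i is at most 1 + max label among items < i).
all_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxb) {
    i <- length(prefix) + 1L
    if (i > n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (b in seq_len(maxb + 1L)) rec(c(prefix, b), max(maxb, b))
  }
  rec(integer(0), 0L)
  res
}

# Direct pair-enumeration scores: loops over every unordered item pair and
# averages the co-cluster indicator within/between talkers. Deliberately
# avoids the package's matrix construction.
pair_enum_scores <- function(blocks, talkers) {
  n <- length(blocks)
  same_t <- numeric(0)
  diff_t <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      co <- as.numeric(blocks[i] == blocks[j])
      if (talkers[i] == talkers[j]) same_t <- c(same_t, co)
      else diff_t <- c(diff_t, co)
    }
  }
  list(tt = mean(same_t), ta = mean(diff_t), ncl = length(unique(blocks)))
}

# Brute-force two-sided Mann-Whitney p: enumerate every assignment of the
# pooled observations into groups of the observed sizes and count rank sums
# at least as far from the null expectation as the observed one.
brute_mw_p <- function(a, b) {
  na <- length(a)
  x <- c(a, b)
  n <- length(x)
  r <- rank(x)
  obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  combs <- utils::combn(n, na)
  s <- apply(combs, 2, function(idx) sum(r[idx]))
  mean(abs(s - mu) >= abs(obs - mu) - 1e-9)
}

# Response built from an integer block vector in manifest item order.
response_from_blocks <- function(manifest, blocks, id = "P1",
                                 tf = "HI", af = "HI") {
  sorting_response(id, setNames(paste0("c", blocks), manifest$item_id), tf, af)
}

# Uneven test manifest: first n items of a (4, k, 0) design.
manifest_of_size <- function(n, n_talkers = 2) {
  m <- generate_manifest(4, n_talkers, 0)
  m[seq_len(n), , drop = FALSE]
}

# Scores frame for synthetic groups given per-group score vectors.
scores_frame <- function(values_by_group, dv = "telling_together") {
  rows <- lapply(names(values_by_group), function(g) {
    tf <- sub("^T(HI|LO)_A(HI|LO)$", "\\1", g)
    af <- sub("^T(HI|LO)_A(HI|LO)$", "\\2", g)
    v <- values_by_group[[g]]
    df <- data.frame(participant_id = paste0(g, "_", seq_along(v)),
                     talker_familiarity = tf, accent_familiarity = af,
                     n_clusters = v, telling_together = v, telling_apart = v,
                     stringsAsFactors = FALSE)
    df
  })
  do.call(rbind, rows)
}
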
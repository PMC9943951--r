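#' Behavioural presets for simulated listener groups
#'
#' The generator describes a listener by two parameters. `split_rate` is the
#' expected number of sub-clusters a single talker's recordings are broken
#' into (1 = the listener always keeps a talker together; larger values model
#' the failure to tell a variable voice "together"). `merge_prob` is the
#' probability that a matched pair of sub-clusters from different talkers is
#' merged, modelling "telling apart" errors. Splitting drives the
#' telling-together score and the cluster count; merging drives the
#' telling-apart score and pulls the cluster count back down.
#'
#' @param split_rate expected sub-clusters per talker (>= 1).
#' @param merge_prob per-matched-pair merge probability in \[0, 1\].
#' @param label group name.
#' @return A list of class `group_preset`.
#' @export
group_preset <- function(split_rate, merge_prob, label = "group") {
  if (split_rate < 1) stop("`split_rate` must be >= 1")
  if (merge_prob < 0 || merge_prob > 1) stop("`merge_prob` must be in [0, 1]")
  structure(list(split_rate = split_rate, merge_prob = merge_prob,
                 label = label), class = "group_preset")
}

#' Default presets for the four familiarity groups
#'
#' One preset per Talker x Accent familiarity cell, calibrated by Monte-Carlo
#' so that simulated cohorts reproduce the group-level medians typical of the
#' two-talker televised-voice design this package targets (telling-together
#' medians near .82/.50/.34/.23 and cluster-count medians near 3/4/5.5/5 for
#' THI_AHI/THI_ALO/TLO_AHI/TLO_ALO) and, in particular, the qualitative group
#' ordering on all three dependent measures: listeners familiar with both the
#' talkers and the accent sort best, listeners familiar with neither worst.
#'
#' @return Named list of four [group_preset()] values
#'   (`THI_AHI`, `THI_ALO`, `TLO_AHI`, `TLO_ALO`).
#' @export
default_presets <- function() {
  list(
    THI_AHI = group_preset(1.40, 0.08, "THI_AHI"),
    THI_ALO = group_preset(2.30, 0.55, "THI_ALO"),
    TLO_AHI = group_preset(3.30, 0.45, "TLO_AHI"),
    TLO_ALO = group_preset(4.60, 0.85, "TLO_ALO")
  )
}

# Stirling numbers of the second kind, S[i + 1, j + 1] = S(i, j), as doubles.
stirling2_table <- function(n) {
  S <- matrix(0, n + 1, n + 1)
  S[1, 1] <- 1
  for (i in seq_len(n))
    for (j in seq_len(i))
      S[i + 1, j + 1] <- j * S[i, j + 1] + S[i, j]
  S
}

#' Uniform random set partition into exactly k blocks
#'
#' Samples uniformly over all partitions of `n` items into exactly `k`
#' non-empty blocks, by walking the Stirling-number recurrence
#' `S(n, k) = S(n-1, k-1) + k S(n-1, k)`: the last item is a singleton with
#' probability `S(n-1, k-1)/S(n, k)`, otherwise it joins one of the `k`
#' blocks of a uniform partition of the remaining items.
#'
#' @param n number of items (>= 1).
#' @param k number of blocks (1 <= k <= n).
#' @return integer vector of block labels in `1..k`, one per item.
#' @export
rpartition_k <- function(n, k) {
  if (k < 1 || k > n) stop("need 1 <= k <= n")
  S <- stirling2_table(n)
  rec <- function(i, j) {
    if (j == i) return(seq_len(i))
    if (j == 1) return(rep(1L, i))
    if (stats::runif(1) < S[i, j] / S[i + 1, j + 1]) {
      c(rec(i - 1L, j - 1L), j)
    } else {
      c(rec(i - 1L, j), sample.int(j, 1))
    }
  }
  rec(as.integer(n), as.integer(k))
}

#' Simulate one participant's sorting response
#'
#' Two-stage generative model of sorting behaviour. Stage 1 (splitting): for
#' each talker, the number of sub-clusters k is drawn as 1 + Poisson
#' (`split_rate` - 1), truncated to the number of that talker's items, and the
#' items are partitioned uniformly at random into k non-empty sub-clusters.
#' Stage 2 (merging): sub-clusters of different talkers are matched one-to-one
#' at random (for two talkers, `min(k1, k2)` random pairs) and each matched
#' pair is merged independently with probability `merge_prob`; a single pass,
#' no cascading merges. Vigilance items are placed in a cluster of their own
#' unless `vigilance = "scramble"` plants a failed attention check.
#'
#' @param preset a [group_preset()].
#' @param manifest a [generate_manifest()] manifest.
#' @param participant_id,talker_familiarity,accent_familiarity identity and
#'   group metadata for the emitted response.
#' @param vigilance `"isolate"` (correct check) or `"scramble"` (planted
#'   failure: the duplicated clips end up in different clusters).
#' @return a [sorting_response()]; always valid against `manifest`.
#' @examples
#' set.seed(7)
#' m <- generate_manifest()
#' r <- simulate_response(group_preset(1, 0), m)
#' unlist(score_response(r, m))  # perfect sort: 2, 1, 0
#' @export
simulate_response <- function(preset, manifest, participant_id = "P1",
                              talker_familiarity = "HI",
                              accent_familiarity = "HI",
                              vigilance = c("isolate", "scramble")) {
  vigilance <- match.arg(vigilance)
  test <- test_items(manifest)
  talkers <- unique(test$talker_id)
  cl <- character(nrow(test))
  names(cl) <- test$item_id
  sub_talker <- character(0)  # talker of each sub-cluster label
  for (t in talkers) {
    idx <- which(test$talker_id == t)
    nt <- length(idx)
    k <- min(1L + stats::rpois(1, preset$split_rate - 1), nt)
    blocks <- if (k == 1) rep(1L, nt) else rpartition_k(nt, k)
    labs <- sprintf("%s.s%d", t, seq_len(k))
    cl[idx] <- labs[blocks]
    sub_talker <- c(sub_talker, stats::setNames(rep(t, k), labs))
  }
  # stage 2: one-pass random matching across talkers, merge with merge_prob
  if (preset$merge_prob > 0 && length(sub_talker) > 1) {
    ord <- sample(names(sub_talker))
    avail <- rep(TRUE, length(ord))
    for (i in seq_along(ord)) {
      if (!avail[i]) next
      j <- which(avail & sub_talker[ord] != sub_talker[ord[i]] &
                   seq_along(ord) > i)
      if (!length(j)) next
      j <- j[1]
      avail[c(i, j)] <- FALSE
      if (stats::runif(1) < preset$merge_prob)
        cl[cl == ord[j]] <- ord[i]
    }
  }
  vig <- vigilance_items(manifest)$item_id
  assignment <- cl
  if (length(vig)) {
    vcl <- if (vigilance == "isolate") {
      rep("vig", length(vig))
    } else {
      # plant a failed check: spread the duplicated clips across clusters
      test_cl <- unique(unname(cl))
      if (length(test_cl) >= 2) {
        rep_len(test_cl[c(1, length(test_cl))], length(vig))
      } else {
        c(test_cl[1], rep("vig", length(vig) - 1L))
      }
    }
    assignment <- c(cl, stats::setNames(vcl, vig))
  }
  sorting_response(participant_id, assignment[manifest$item_id],
                   talker_familiarity, accent_familiarity)
}

#' Configuration for a simulated cohort
#'
#' Defaults mirror the canonical study conditions: a 2 x 15 + 2 vigilance
#' manifest and four familiarity groups. `planted` requests a number of
#' participants per exclusion rule; planted participants are spread across
#' the groups deterministically (round-robin over the interleaved group
#' order) so every group can contribute violations.
#'
#' @param group_sizes named integer vector; names must match the preset names.
#' @param presets named list of [group_preset()] values.
#' @param n_per_talker,n_talkers,n_vigilance manifest composition.
#' @param seed mandatory integer seed; the cohort is a pure function of the
#'   config.
#' @param planted named counts over
#'   `vigilance_fail, prior_familiarity, insufficient_exposure,
#'   single_cluster_anomaly` (missing names = 0).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(THI_AHI = 32, THI_ALO = 29,
                                          TLO_AHI = 32, TLO_ALO = 33),
                          presets = default_presets(),
                          n_per_talker = 15, n_talkers = 2, n_vigilance = 2,
                          seed = 1,
                          planted = c(vigilance_fail = 0,
                                      prior_familiarity = 0,
                                      insufficient_exposure = 0,
                                      single_cluster_anomaly = 0)) {
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% names(presets)))
    stop("`group_sizes` must be named after presets")
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  rules <- c("vigilance_fail", "prior_familiarity",
             "insufficient_exposure", "single_cluster_anomaly")
  pl <- stats::setNames(rep(0L, length(rules)), rules)
  if (length(planted)) {
    if (is.null(names(planted)) || !all(names(planted) %in% rules))
      stop("`planted` names must be among: ", paste(rules, collapse = ", "))
    pl[names(planted)] <- as.integer(planted)
  }
  if (sum(pl) > sum(group_sizes))
    stop("more planted violations than participants")
  if (is.null(seed)) stop("`seed` is mandatory")
  structure(list(group_sizes = group_sizes, presets = presets,
                 n_per_talker = n_per_talker, n_talkers = n_talkers,
                 n_vigilance = n_vigilance, seed = as.integer(seed),
                 planted = pl),
            class = "cohort_config")
}

#' Simulate a full cohort with ground-truth exclusion ledger
#'
#' Generates the manifest, one response per participant from that group's
#' preset, the questionnaire metadata, and a ground-truth ledger recording
#' which participants carry planted QC violations. Participants not planted
#' as single-cluster anomalies are re-drawn (up to 100 attempts) if a merge
#' pass happens to collapse all test items into one cluster: the cohort
#' generator conditions on QC-clean behaviour except where a violation is
#' planted, so the ledger is exhaustive and retention accounting is exact.
#' The result is reproducible: the same config (including seed) yields an
#' identical cohort.
#'
#' @param config a [cohort_config()].
#' @return A list of class `sorting_cohort`: `manifest`, `responses` (list of
#'   [sorting_response()]), `metadata` (questionnaire flags), `truth`
#'   (data frame `participant_id,outcome`), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  manifest <- generate_manifest(config$n_per_talker, config$n_talkers,
                                config$n_vigilance)
  sizes <- config$group_sizes
  n <- sum(sizes)
  grp <- rep(names(sizes), sizes)
  ids <- sprintf("P%03d", seq_len(n))
  # interleave groups (1st of each, 2nd of each, ...) and plant rules along
  # that order so violations are spread across groups
  within_rank <- stats::ave(seq_len(n), grp, FUN = seq_along)
  interleaved <- order(within_rank, match(grp, names(sizes)))
  planted_outcome <- rep("retained", n)
  rules <- rep(names(config$planted), config$planted)
  if (length(rules))
    planted_outcome[interleaved[seq_along(rules)]] <- rules
  responses <- vector("list", n)
  for (i in seq_len(n)) {
    preset <- config$presets[[grp[i]]]
    tf <- sub("^T(HI|LO)_A(HI|LO)$", "\\1", grp[i])
    af <- sub("^T(HI|LO)_A(HI|LO)$", "\\2", grp[i])
    out <- planted_outcome[i]
    if (out == "vigilance_fail") {
      r <- simulate_response(preset, manifest, ids[i], tf, af,
                             vigilance = "scramble")
    } else if (out == "single_cluster_anomaly") {
      lab <- ifelse(manifest$is_vigilance, "vig", "all")
      r <- sorting_response(ids[i], stats::setNames(lab, manifest$item_id),
                            tf, af)
    } else {
      for (try in seq_len(100)) {
        r <- simulate_response(preset, manifest, ids[i], tf, af)
        if (check_single_cluster(r, manifest)) break
      }
    }
    responses[[i]] <- r
  }
  metadata <- data.frame(
    participant_id = ids,
    prior_familiarity = planted_outcome == "prior_familiarity",
    insufficient_exposure = planted_outcome == "insufficient_exposure",
    stringsAsFactors = FALSE
  )
  structure(list(manifest = manifest, responses = responses,
                 metadata = metadata,
                 truth = data.frame(participant_id = ids,
                                    outcome = planted_outcome,
                                    stringsAsFactors = FALSE),
                 config = config),
            class = "sorting_cohort")
}

#' @export
print.sorting_cohort <- function(x, ...) {
  cat(sprintf("Simulated sorting cohort: %d participants, %d items (seed %d)\n",
              length(x$responses), nrow(x$manifest), x$config$seed))
  print(table(group = rep(names(x$config$group_sizes), x$config$group_sizes)))
  np <- sum(x$truth$outcome != "retained")
  if (np) cat(sprintf("planted QC violations: %d\n", np))
  invisible(x)
}
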
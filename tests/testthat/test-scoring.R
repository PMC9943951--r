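test_that("response matrix encodes co-clustering of test items only", {
  m <- generate_manifest()
  one <- sorting_response("P1", setNames(
    ifelse(m$is_vigilance, "vig", "mega"), m$item_id))
  M1 <- build_response_matrix(one, m)
  expect_equal(dim(M1), c(30, 30))
  expect_true(all(M1[upper.tri(M1)] == 1))

  singles <- sorting_response("P2", setNames(
    paste0("s", seq_len(nrow(m))), m$item_id))
  M2 <- build_response_matrix(singles, m)
  expect_true(all(M2[upper.tri(M2)] == 0))
  expect_true(isSymmetric(unclass(M1)) && isSymmetric(unclass(M2)))

  # 4-item toy design: clusters {a1, a2, b1}, {b2}
  tm <- generate_manifest(2, 2, 0)
  toy <- response_from_blocks(tm, c(1, 1, 1, 2))
  M <- build_response_matrix(toy, tm)
  expect_equal(M["T1_01", "T1_02"], 1)
  expect_equal(M["T1_01", "T2_01"], 1)
  expect_equal(M["T1_02", "T2_01"], 1)
  expect_equal(M["T1_01", "T2_02"], 0)
  expect_equal(M["T1_02", "T2_02"], 0)
  expect_equal(M["T2_01", "T2_02"], 0)
})

test_that("the three measures hit their defining anchor cases", {
  m <- generate_manifest()
  truth <- ground_truth_response(m)
  s <- score_response(truth, m)
  expect_equal(s$n_clusters, 2)
  expect_equal(s$telling_together, 1)
  expect_equal(s$telling_apart, 0)

  mega <- sorting_response("P1", setNames(
    ifelse(m$is_vigilance, "vig", "one"), m$item_id))
  expect_equal(unclass(unlist(score_response(mega, m))),
               c(n_clusters = 1, telling_together = 1, telling_apart = 1))

  singles <- sorting_response("P2", setNames(
    paste0("s", seq_len(nrow(m))), m$item_id))
  expect_equal(unclass(unlist(score_response(singles, m))),
               c(n_clusters = 30, telling_together = 0, telling_apart = 0))

  tm <- generate_manifest(2, 2, 0)
  toy <- score_response(response_from_blocks(tm, c(1, 1, 1, 2)), tm)
  expect_equal(toy$telling_together, 0.5)  # pairs (a1,a2)=1, (b1,b2)=0
  expect_equal(toy$telling_apart, 0.5)     # cross pairs 1,1,0,0
})

test_that("vigilance-only clusters never count as perceived talkers", {
  m <- generate_manifest(2, 2, 2)
  r <- sorting_response("P1", setNames(
    c("a", "a", "a", "b", "vig", "vig"), m$item_id))
  expect_equal(count_clusters(r, m), 2)
  # a vigilance item stranded in a test cluster: its items still count
  r2 <- sorting_response("P2", setNames(
    c("a", "a", "b", "b", "a", "vig"), m$item_id))
  expect_equal(count_clusters(r2, m), 2)
})

test_that("undefined scores are signalled, not silently computed", {
  # single item per talker: no within-talker pair exists
  m1 <- generate_manifest(2, 2, 0)[c(1, 3), ]
  r1 <- response_from_blocks(m1, c(1, 2))
  M1 <- build_response_matrix(r1, m1)
  expect_error(telling_together(M1), "telling-together undefined")
  expect_equal(telling_apart(M1), 0)
  # invalid response rejected with the offending ids named
  m <- generate_manifest()
  bad <- sorting_response("P9", ground_truth_response(m)$assignment[-3])
  expect_error(build_response_matrix(bad, m), m$item_id[3])
})

test_that("matrix scores equal direct pair enumeration on random partitions", {
  m <- generate_manifest()
  talkers <- m$talker_id[!m$is_vigilance]
  set.seed(404)
  for (i in 1:100) {
    blocks <- sample.int(sample(1:10, 1), nrow(m), replace = TRUE)
    r <- response_from_blocks(m, blocks)
    s <- score_response(r, m)
    o <- pair_enum_scores(blocks[!m$is_vigilance], talkers)
    expect_equal(s$telling_together, o$tt)
    expect_equal(s$telling_apart, o$ta)
    expect_equal(s$n_clusters, o$ncl)
  }
})

test_that("scores are invariant under cluster relabeling and item reorder", {
  m <- generate_manifest()
  set.seed(11)
  for (i in 1:25) {
    blocks <- sample.int(6, nrow(m), replace = TRUE)
    r <- response_from_blocks(m, blocks)
    # relabel clusters with random strings, shuffle the assignment order
    labs <- vapply(seq_len(10), function(j)
      paste(sample(letters, 8), collapse = ""), character(1))
    relabeled <- sorting_response("P", setNames(
      labs[blocks], m$item_id)[sample(nrow(m))])
    expect_equal(unlist(score_response(relabeled, m)),
                 unlist(score_response(r, m)))
  }
})

test_that("merging two clusters never decreases either score", {
  m <- generate_manifest()
  set.seed(12)
  for (i in 1:40) {
    blocks <- sample.int(8, nrow(m), replace = TRUE)
    if (length(unique(blocks)) < 2) next
    s0 <- score_response(response_from_blocks(m, blocks), m)
    two <- sample(unique(blocks), 2)
    merged <- ifelse(blocks == two[2], two[1], blocks)
    s1 <- score_response(response_from_blocks(m, merged), m)
    expect_gte(s1$telling_together, s0$telling_together)
    expect_gte(s1$telling_apart, s0$telling_apart)
  }
})

test_that("perfect scores occur iff the partition is the talker partition", {
  m <- generate_manifest(3, 2, 0)
  truth_blocks <- as.integer(factor(m$talker_id))
  for (p in all_partitions(6)) {
    s <- score_response(response_from_blocks(m, p), m)
    perfect <- s$telling_together == 1 && s$telling_apart == 0
    expect_equal(perfect, identical(as.integer(p), truth_blocks))
    if (perfect) expect_equal(s$n_clusters, 2)
  }
})

test_that("cohort scoring emits one labelled row per participant", {
  cohort <- simulate_cohort(cohort_config(
    group_sizes = c(THI_AHI = 4, TLO_ALO = 3), seed = 2))
  sc <- score_cohort(cohort$responses, cohort$manifest)
  expect_equal(nrow(sc), 7)
  expect_setequal(names(sc),
                  c("participant_id", "talker_familiarity",
                    "accent_familiarity", "n_clusters", "telling_together",
                    "telling_apart"))
  expect_true(all(sc$telling_together >= 0 & sc$telling_together <= 1))
  expect_true(all(sc$telling_apart >= 0 & sc$telling_apart <= 1))
})
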
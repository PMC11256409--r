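test_that("pair similarity merges segment intervals on the shorter sequence", {
  segs <- tibble::tibble(q_start = c(1, 301), q_end = c(400, 700),
                         s_start = c(11, 311), s_end = c(410, 710),
                         percent_identity = c(96, 96))
  out <- pair_similarity(segs, len_query = 1000, len_subject = 5000)
  expect_equal(out$coverage, 0.7)  # union [1,700] = 700 bp of 1000

  # identity is the segment-length-weighted mean
  segs2 <- tibble::tibble(q_start = c(1, 501), q_end = c(200, 700),
                          s_start = c(1, 501), s_end = c(200, 700),
                          percent_identity = c(100, 90))
  expect_equal(pair_similarity(segs2, 1000, 2000)$identity, 95)

  empty <- segs[0, ]
  expect_equal(pair_similarity(empty, 1000, 2000),
               list(identity = 0, coverage = 0))
})

test_that("greedy clustering follows descending length with centroid-only tests", {
  lens <- c(A = 10000, B = 9000, C = 5000)
  sims <- tibble::tibble(query_id = "A", subject_id = "B",
                         identity = 96, coverage = 0.8)
  out <- cluster_votus(lens, sims)
  expect_equal(sort(out$representative_id[match(c("A", "B", "C"),
                                                out$member_id)]),
               c("A", "A", "C"))

  # chain A-B pass, B-C pass, A-C fail: C is tested only against centroid A
  sims2 <- tibble::tibble(
    query_id = c("A", "B"), subject_id = c("B", "C"),
    identity = c(96, 97), coverage = c(0.8, 0.9)
  )
  out2 <- cluster_votus(lens, sims2)
  expect_equal(out2$representative_id[out2$member_id == "C"], "C")
  expect_equal(out2$representative_id[out2$member_id == "B"], "A")
})

test_that("identical-length ties break lexicographically and the representative is longest", {
  lens <- c(Z = 4000, M = 4000, A = 4000)
  sims <- tidyr::expand_grid(query_id = names(lens),
                             subject_id = names(lens)) |>
    dplyr::filter(.data$query_id != .data$subject_id) |>
    dplyr::mutate(identity = 100, coverage = 1)
  out <- cluster_votus(lens, sims)
  expect_equal(unique(out$representative_id), "A")
  agg <- dplyr::group_by(out, .data$representative_id) |>
    dplyr::summarise(maxlen = max(.data$length))
  rep_len <- lens[agg$representative_id]
  expect_true(all(rep_len == agg$maxlen))
})

test_that("greedy clustering equals an independent reimplementation on random inputs", {
  withr::with_seed(77, {
    n <- 50
    ids <- sprintf("s%02d", 1:n)
    lens <- setNames(sample(3000:50000, n), ids)
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.15
    sims <- tibble::tibble(
      query_id = pairs[keep, 1], subject_id = pairs[keep, 2],
      identity = runif(sum(keep), 90, 100),
      coverage = runif(sum(keep), 0.5, 1)
    )
  })
  out <- cluster_votus(lens, sims)
  key <- paste(c(sims$query_id, sims$subject_id),
               c(sims$subject_id, sims$query_id), sep = "|")
  id_lut <- setNames(rep(sims$identity, 2), key)
  cov_lut <- setNames(rep(sims$coverage, 2), key)
  sim_fun <- function(a, b) {
    k <- paste(a, b, sep = "|")
    if (is.na(id_lut[k])) c(0, 0) else c(id_lut[[k]], cov_lut[[k]])
  }
  expected <- oracle_greedy(lens, sim_fun)
  got <- setNames(out$representative_id, out$member_id)[names(expected)]
  expect_equal(unname(got), unname(expected))
  # partition: cluster sizes sum to input size
  expect_equal(nrow(out), n)
  # representative at least as long as every member
  by_rep <- split(out$length, out$representative_id)
  for (rep_id in names(by_rep)) {
    expect_gte(lens[[rep_id]], max(by_rep[[rep_id]]))
  }
})

test_that("raising the identity threshold never decreases the cluster count", {
  withr::with_seed(5, {
    ids <- sprintf("t%02d", 1:20)
    lens <- setNames(sample(3000:20000, 20), ids)
    pairs <- t(combn(ids, 2))
    sims <- tibble::tibble(
      query_id = pairs[, 1], subject_id = pairs[, 2],
      identity = runif(nrow(pairs), 85, 100),
      coverage = runif(nrow(pairs), 0.5, 1)
    )
  })
  counts <- vapply(c(90, 93, 95, 97, 99), function(thr) {
    length(unique(cluster_votus(lens, sims,
                                id_threshold = thr)$representative_id))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("external-only clusters are dropped, anchored clusters kept", {
  cat <- tibble::tibble(
    representative_id = c("r1", "r1", "r2", "r2", "r3"),
    member_id = c("r1", "e1", "r2", "e2", "r3"),
    length = c(9000, 8000, 7000, 6500, 5000)
  )
  src <- c(r1 = "study", e1 = "external", r2 = "external", e2 = "external",
           r3 = "study")
  out <- integrate_external(cat, src)
  expect_setequal(unique(out$representative_id), c("r1", "r3"))
  expect_error(integrate_external(cat, src[-1]), "missing source label")
  # no external members: identity
  cat2 <- cat[cat$member_id %in% c("r1", "r3"), ]
  out2 <- integrate_external(cat2, c(r1 = "study", r3 = "study"))
  expect_equal(out2$member_id, cat2$member_id)
})

test_that("quality tiers honour the completeness and contamination cutoffs", {
  out <- quality_tier(c(100, 90, 89.9, 49.9), c(0, 5, 12, 9))
  expect_equal(out$tier, c("complete", "high", "medium", "low"))
  expect_equal(out$low_contamination, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(quality_tier(101, 0), "\\[0, 100\\]")
  expect_error(quality_tier(50, -1), "\\[0, 100\\]")
})

test_that("unknown ids in the similarity table are rejected", {
  expect_error(
    cluster_votus(c(A = 1000),
                  tibble::tibble(query_id = "A", subject_id = "Q",
                                 identity = 99, coverage = 1)),
    "unknown id"
  )
})
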
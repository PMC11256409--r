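test_that("invalid configurations are rejected with the violated invariant named", {
  expect_error(sim_config(n_votus = 5, n_planted_case_enriched = 4,
                          n_planted_control_enriched = 2),
               "planted vOTUs cannot exceed n_votus")
  expect_error(sim_config(effect_fold = 0.5), "effect_fold")
  expect_error(sim_config(dropout_rate = 1.5), "dropout_rate")
  expect_error(sim_config(genome_length_range = c(5000, 2000)),
               "genome_length_range")
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- tiny_config(seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$depth_store, b$depth_store)
  expect_identical(a$truth, b$truth)
  expect_identical(a$contig_features, b$contig_features)
  expect_identical(a$protein_hits, b$protein_hits)
})

test_that("per-sample compositions are closed before depth simulation", {
  st <- simulate_cohort(tiny_config(seed = 3), depths = FALSE)
  sums <- tapply(st$abundance$abundance, st$abundance$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(st$abundance$abundance >= 0 & st$abundance$abundance <= 1))
})

test_that("a null cohort (fold 1) keeps planted labels but no built-in effect", {
  cfg <- tiny_config(seed = 5, effect_fold = 1)
  st <- simulate_cohort(cfg, depths = FALSE)
  expect_equal(sum(st$truth$planted == "case_enriched"), 2)
  expect_equal(sum(st$truth$planted == "control_enriched"), 2)
})

test_that("sample sheet pairs every subject with exactly one VLP and one bulk sample", {
  st <- simulate_cohort(tiny_config(seed = 2), depths = FALSE)
  per_subj <- table(st$samples$subject_id, st$samples$modality)
  expect_true(all(per_subj == 1))
  expect_setequal(unique(st$samples$group), c("case", "control"))
})

test_that("depth vectors are Poisson draws of the genome length", {
  v <- generate_depth_vector(10000, 5, seed = 1)
  expect_length(v, 10000)
  expect_true(all(v >= 0) && all(v == floor(v)))
  # Poisson CLT bound: mean within 5 * (1 +/- 4 / sqrt(1e4))
  expect_lt(abs(mean(v) - 5), 5 * 4 / sqrt(10000))
  expect_identical(v, generate_depth_vector(10000, 5, seed = 1))
  expect_identical(generate_depth_vector(50, 0, seed = 2), rep(0L, 50))
  expect_error(generate_depth_vector(0, 5, seed = 1), "positive integer")
})

test_that("planted abundance ratio between groups stays near the configured fold", {
  # fold 4: group mean ratio of planted vOTUs in [2, 8] in >= 19/20 seeds
  ok <- vapply(1:20, function(s) {
    st <- simulate_cohort(sim_config(seed = 100 + s), depths = FALSE)
    ab <- dplyr::left_join(st$abundance, st$samples, by = "sample_id") |>
      dplyr::filter(.data$modality == "bulk") |>
      dplyr::left_join(st$truth[, c("votu_id", "planted")], by = "votu_id") |>
      dplyr::filter(.data$planted == "case_enriched")
    ratio <- mean(ab$abundance[ab$group == "case"]) /
      mean(ab$abundance[ab$group == "control"])
    ratio >= 2 && ratio <= 8
  }, logical(1))
  expect_gte(sum(ok), 19)
})

test_that("truth labels and tables round-trip through serialization", {
  st <- simulate_cohort(tiny_config(seed = 9))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  expect_equal(as.data.frame(back$truth), as.data.frame(st$truth))
  expect_equal(as.data.frame(back$samples), as.data.frame(st$samples))
  expect_identical(back$genomes, st$genomes)
  # depth vectors identical after the position/depth TSV round trip
  key <- paste(st$depth_store$sample_id, st$depth_store$votu_id)
  bkey <- paste(back$depth_store$sample_id, back$depth_store$votu_id)
  expect_setequal(bkey, key)
  i <- match(key[1], bkey)
  expect_equal(back$depth_store$depths[[i]],
               as.numeric(st$depth_store$depths[[1]]))
})

test_that("synthetic evidence is consistent with the planted truth", {
  st <- simulate_cohort(tiny_config(seed = 4), depths = FALSE)
  # every vOTU contig passes triage; decoys fall where designed
  tr <- triage_contigs(st$contig_features)
  merged <- dplyr::inner_join(tr, st$contig_truth, by = "contig_id")
  expect_equal(merged$verdict, merged$expected_verdict)
  # duplicate contigs collapse into their parent vOTU
  viral <- tr$contig_id[tr$verdict == "viral"]
  lens <- setNames(st$contig_features$length, st$contig_features$contig_id)
  cat <- cluster_votus(lens[viral], st$alignments)
  for (i in seq_len(nrow(st$duplicates))) {
    expect_equal(
      cat$representative_id[cat$member_id == st$duplicates$contig_id[i]],
      st$duplicates$parent_id[i]
    )
  }
})
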
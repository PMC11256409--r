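test_that("Wilcoxon exact p matches full enumeration on worked examples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 2 / 6)
  expect_equal(wilcoxon_rank_sum(c(5, 6, 7), c(5, 6, 7)), 1)
})

test_that("Wilcoxon exact p equals the enumeration oracle for all small designs", {
  withr::with_seed(17, {
    for (n1 in 1:5) {
      for (n2 in n1:(10 - n1)) {
        x <- sample(seq(1, 100), n1)
        y <- sample(setdiff(seq(1, 100), x), n2)
        expect_equal(wilcoxon_rank_sum(x, y), oracle_wilcoxon_exact(x, y),
                     info = sprintf("n1=%d n2=%d", n1, n2))
      }
    }
  })
})

test_that("BH adjustment matches the literal step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.001, 1.0)), c(0.002, 1.0))
  withr::with_seed(23, {
    for (i in 1:30) {
      p <- runif(sample(2:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p))
      expect_true(all(q >= p))
      expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher exact p matches hypergeometric enumeration; OR is the cross-product", {
  out <- fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(out$p_value, 34 / 70)
  expect_equal(out$odds_ratio, 9)
  out2 <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(out2$p_value, 2 / choose(20, 10))
  expect_identical(out2$odds_ratio, Inf)
  out3 <- fisher_exact_2x2(matrix(1, 2, 2))
  expect_equal(out3$p_value, 1)
  expect_equal(out3$odds_ratio, 1)
  expect_warning(out4 <- fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2,
                                                 byrow = TRUE)),
                 "zero margin")
  expect_equal(out4$p_value, 1)
  withr::with_seed(29, {
    for (i in 1:100) {
      tbl <- matrix(rpois(4, 5), 2)
      if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) next
      expect_equal(fisher_exact_2x2(tbl)$p_value, oracle_fisher_p(tbl),
                   tolerance = 1e-9)
    }
  })
})

# Deterministic dual-modality profiles with one clear case-enriched vOTU,
# one vOTU significant in VLP only, and one significant with opposite
# directions across modalities.
mk_sig_fixture <- function() {
  n <- 12  # per group per modality
  samples <- tibble::tibble(
    sample_id = c(sprintf("v_case%02d", 1:n), sprintf("v_ctrl%02d", 1:n),
                  sprintf("b_case%02d", 1:n), sprintf("b_ctrl%02d", 1:n)),
    group = rep(rep(c("case", "control"), each = n), 2),
    modality = rep(c("vlp", "bulk"), each = 2 * n)
  )
  base <- seq(0.1, 0.2, length.out = n)
  # v1 = concordant case-up; v2 = VLP-only; v3 = discordant directions
  mk <- function(ids, v1, v2, v3) {
    tibble::tibble(
      sample_id = rep(ids, each = 3),
      votu_id = rep(c("v1", "v2", "v3"), length(ids)),
      abundance = as.vector(rbind(v1, v2, v3))
    )
  }
  vlp <- dplyr::bind_rows(
    mk(samples$sample_id[1:n], base + 1, base + 1, base + 1),       # cases
    mk(samples$sample_id[n + 1:n], base, base, base)                # controls
  )
  bulk <- dplyr::bind_rows(
    mk(samples$sample_id[2 * n + 1:n], base + 1, base, base),       # cases
    mk(samples$sample_id[3 * n + 1:n], base, base, base + 1)        # controls
  )
  list(vlp = vlp, bulk = bulk, samples = samples)
}

test_that("signature status needs significance and direction agreement in both modalities", {
  fx <- mk_sig_fixture()
  sig <- call_signatures(fx$vlp, fx$bulk, fx$samples)
  res <- sig$results
  expect_equal(res$status[res$votu_id == "v1"], "case_enriched")
  # significant in VLP only -> not a signature
  expect_lt(res$q_vlp[res$votu_id == "v2"], 0.05)
  expect_equal(res$status[res$votu_id == "v2"], "not_significant")
  # significant in both but opposite directions -> not a signature
  expect_lt(res$q_vlp[res$votu_id == "v3"], 0.05)
  expect_lt(res$q_bulk[res$votu_id == "v3"], 0.05)
  expect_equal(res$status[res$votu_id == "v3"], "not_significant")
  # status partition covers all vOTUs
  expect_equal(nrow(res), 3)
  expect_true(all(res$q_vlp >= res$p_vlp - 1e-15, na.rm = TRUE))
})

test_that("alpha = 1 makes every tested direction-consistent vOTU a signature", {
  fx <- mk_sig_fixture()
  sig <- call_signatures(fx$vlp, fx$bulk, fx$samples, alpha = 1)
  res <- sig$results
  expect_equal(res$status[res$votu_id == "v1"], "case_enriched")
  expect_equal(res$status[res$votu_id == "v3"], "not_significant") # discordant
})

test_that("profiles with mismatched vOTU sets are rejected", {
  fx <- mk_sig_fixture()
  bad <- dplyr::filter(fx$bulk, .data$votu_id != "v3")
  expect_error(call_signatures(fx$vlp, bad, fx$samples), "same vOTU set")
})

test_that("prevalence-filtered vOTUs are reported as not_tested", {
  fx <- mk_sig_fixture()
  # v3 absent from almost all VLP samples
  vlp <- dplyr::mutate(fx$vlp, abundance = ifelse(.data$votu_id == "v3", 0,
                                                  .data$abundance))
  sig <- call_signatures(vlp, fx$bulk, fx$samples)
  expect_equal(sig$results$status[sig$results$votu_id == "v3"], "not_tested")
})

test_that("functional occurrence comparison uses Fisher + BH over functions", {
  groups <- setNames(rep(c("case_enriched", "control_enriched"), each = 10),
                     sprintf("v%02d", 1:20))
  pres <- matrix(0, 3, 20,
                 dimnames = list(c("f_all_case", "f_none", "f_even"),
                                 names(groups)))
  pres["f_all_case", 1:10] <- 1
  pres["f_even", c(1:5, 11:15)] <- 1
  out <- functional_enrichment(pres, groups)
  expect_equal(out$p_value[out$function_id == "f_all_case"],
               2 / choose(20, 10))
  expect_identical(out$odds_ratio[out$function_id == "f_all_case"], Inf)
  expect_equal(out$p_value[out$function_id == "f_none"], 1)
  expect_equal(out$occurrence_case[out$function_id == "f_even"], 0.5)
  expect_false(out$significant[out$function_id == "f_even"])
  expect_equal(out$q_value, bh_adjust(out$p_value))
  expect_error(functional_enrichment(pres, groups[1:10]), "nonempty")
})

test_that("occurrence ratios are plain divisions", {
  groups <- setNames(c(rep("case_enriched", 5), rep("control_enriched", 39)),
                     sprintf("w%02d", 1:44))
  pres <- matrix(0, 1, 44, dimnames = list("f", names(groups)))
  pres["f", 6:10] <- 1  # 5 of the 39 control-enriched vOTUs
  out <- functional_enrichment(pres, groups)
  expect_equal(out$occurrence_control, round(5 / 39, 10), tolerance = 1e-9)
  expect_equal(out$occurrence_control, 0.1282, tolerance = 1e-4)
})
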
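#' Two-sided Wilcoxon rank-sum p-value
#'
#' Mid-ranks are used for ties. The p-value is exact (full enumeration of
#' rank assignments) when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric vectors, each nonempty.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6) # exact, 0.1
#' @export
wilcoxon_rank_sum <- function(x, y) {
  assert_that(length(x) >= 1 && length(y) >= 1,
              "both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: `q(i)` is the minimum over all
#' `p(j) >= p(i)` of `p(j) * m / rank(j)`, capped at 1, returned in the input
#' order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed, propagated).
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  assert_that(all(is.na(p) | (p >= 0 & p <= 1)),
              "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's. The odds ratio is the sample cross-product
#' `(a*d)/(b*c)` — not the conditional maximum-likelihood estimate — so it is
#' a closed-form summary of the observed table; it is `Inf` when `b*c = 0`
#' with `a*d > 0`.
#'
#' @param tbl 2x2 matrix (or something coercible) of nonnegative integer
#'   counts.
#' @return A tibble `odds_ratio`, `p_value`. A zero margin gives `p = 1` and
#'   an undefined (`NA`) odds ratio with a warning.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)) # p = 34/70, OR = 9
#' @export
fisher_exact_2x2 <- function(tbl) {
  m <- matrix(as.numeric(tbl), 2, 2)
  assert_that(all(m >= 0) && all(m == floor(m)),
              "table cells must be nonnegative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warn("degenerate 2x2 table (zero margin); p = 1, odds ratio undefined")
    return(tibble::tibble(odds_ratio = NA_real_, p_value = 1))
  }
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NA_real_
  } else {
    (a * d) / (b * c)
  }
  tibble::tibble(odds_ratio = or,
                 p_value = fisher.test(m)$p.value)
}

#' Call dual-modality case-control vOTU signatures
#'
#' Per modality (VLP and bulk), each vOTU passing a prevalence filter is
#' tested for a case-control difference in relative abundance with the
#' two-sided Wilcoxon rank-sum test; p-values are Benjamini-Hochberg
#' adjusted across all tested vOTUs within the modality. A vOTU becomes a
#' signature only if it is significant (`q < alpha`) in BOTH modalities with
#' the SAME direction of change (sign of mean case minus mean control):
#' `case_enriched`, `control_enriched`, otherwise `not_significant` (or
#' `not_tested` when the prevalence filter excluded it in either modality).
#'
#' Agreement between the two modalities is summarised by a Fisher's exact
#' test over the 2x2 cross-classification of
#' (differential in VLP) x (differential in bulk) membership among all
#' vOTUs tested in both modalities.
#'
#' @param profile_vlp,profile_bulk Long profiles `sample_id`, `votu_id`,
#'   `abundance` for the VLP and bulk datasets (same vOTU set).
#' @param samples Sample sheet tibble `sample_id`, `group` (`"case"` /
#'   `"control"`).
#' @param alpha Per-modality q-value threshold (default 0.05).
#' @param min_prevalence Minimum fraction of a modality's samples in which a
#'   vOTU must be nonzero to be tested (default 0.10).
#' @param pseudocount Added to group means for fold-change reporting only.
#' @return An object of class `virosig_signatures`: list with `results` (a
#'   tibble, one row per vOTU: p/q/direction/fold change per modality plus
#'   `status`) and `concordance` (tibble with the 2x2 counts, odds ratio and
#'   p-value).
#' @export
call_signatures <- function(profile_vlp, profile_bulk, samples,
                            alpha = 0.05, min_prevalence = 0.10,
                            pseudocount = 1e-9) {
  v_votus <- sort(unique(profile_vlp$votu_id))
  b_votus <- sort(unique(profile_bulk$votu_id))
  assert_that(identical(v_votus, b_votus),
              "VLP and bulk profiles must share the same vOTU set")
  assert_that(all(c("sample_id", "group") %in% names(samples)),
              "`samples` needs sample_id and group columns")
  assert_that(all(samples$group %in% c("case", "control")),
              "groups must be 'case' or 'control'")

  one_modality <- function(profile, tag) {
    m <- profile_matrix(profile)
    grp <- samples$group[match(rownames(m), samples$sample_id)]
    assert_that(!anyNA(grp),
                paste0("samples missing from sample sheet in ", tag,
                       " profile"))
    prevalence <- colMeans(m > 0)
    tested <- prevalence >= min_prevalence
    case <- grp == "case"
    p <- rep(NA_real_, ncol(m))
    for (j in which(tested)) {
      p[j] <- wilcoxon_rank_sum(m[case, j], m[!case, j])
    }
    q <- rep(NA_real_, ncol(m))
    q[tested] <- bh_adjust(p[tested])
    mean_case <- colMeans(m[case, , drop = FALSE])
    mean_control <- colMeans(m[!case, , drop = FALSE])
    delta <- mean_case - mean_control
    tibble::tibble(
      votu_id = colnames(m),
      tested = tested,
      p = p, q = q,
      direction = dplyr::case_when(delta > 0 ~ "case_up",
                                   delta < 0 ~ "control_up",
                                   TRUE ~ "flat"),
      fold_change = (mean_case + pseudocount) / (mean_control + pseudocount)
    ) |>
      dplyr::rename_with(\(nm) paste0(nm, "_", tag), -"votu_id")
  }

  vlp <- one_modality(profile_vlp, "vlp")
  bulk <- one_modality(profile_bulk, "bulk")
  res <- dplyr::inner_join(vlp, bulk, by = "votu_id") |>
    dplyr::mutate(
      status = dplyr::case_when(
        !.data$tested_vlp | !.data$tested_bulk ~ "not_tested",
        .data$q_vlp < alpha & .data$q_bulk < alpha &
          .data$direction_vlp == "case_up" &
          .data$direction_bulk == "case_up" ~ "case_enriched",
        .data$q_vlp < alpha & .data$q_bulk < alpha &
          .data$direction_vlp == "control_up" &
          .data$direction_bulk == "control_up" ~ "control_enriched",
        TRUE ~ "not_significant"
      )
    )

  both <- res |>
    dplyr::filter(.data$tested_vlp, .data$tested_bulk)
  diff_vlp <- both$q_vlp < alpha
  diff_bulk <- both$q_bulk < alpha
  tab <- matrix(c(sum(diff_vlp & diff_bulk), sum(diff_vlp & !diff_bulk),
                  sum(!diff_vlp & diff_bulk), sum(!diff_vlp & !diff_bulk)),
                2, 2, byrow = TRUE)
  conc <- suppressWarnings(fisher_exact_2x2(tab)) |>
    dplyr::mutate(both_differential = tab[1, 1],
                  vlp_only = tab[1, 2], bulk_only = tab[2, 1],
                  neither = tab[2, 2], .before = 1)

  structure(list(results = res, concordance = conc, alpha = alpha),
            class = "virosig_signatures")
}

#' @export
print.virosig_signatures <- function(x, ...) {
  n <- table(factor(x$results$status,
                    levels = c("case_enriched", "control_enriched",
                               "not_significant", "not_tested")))
  cat("Dual-modality signature calls (alpha =", x$alpha, "):\n")
  cat(sprintf("  case-enriched: %d, control-enriched: %d, not significant: %d, not tested: %d\n",
              n[["case_enriched"]], n[["control_enriched"]],
              n[["not_significant"]], n[["not_tested"]]))
  cat(sprintf("  VLP/bulk concordance: OR = %.3g, p = %.3g\n",
              x$concordance$odds_ratio, x$concordance$p_value))
  invisible(x)
}

#' @export
tidy.virosig_signatures <- function(x, ...) x$results

#' @export
glance.virosig_signatures <- function(x, ...) {
  tibble::tibble(
    n_votus = nrow(x$results),
    n_case_enriched = sum(x$results$status == "case_enriched"),
    n_control_enriched = sum(x$results$status == "control_enriched"),
    concordance_or = x$concordance$odds_ratio,
    concordance_p = x$concordance$p_value
  )
}

#' Functional occurrence comparison between signature groups
#'
#' For each function, compares the fraction of case-enriched vs
#' control-enriched signature vOTUs carrying at least one gene of that
#' function with Fisher's exact test, Benjamini-Hochberg adjusted across
#' functions.
#'
#' @param presence Logical (or 0/1) matrix, functions x vOTUs.
#' @param signature_groups Named character vector mapping vOTU ids to
#'   `"case_enriched"` or `"control_enriched"`; both groups must be
#'   nonempty.
#' @return A tibble per function: occurrence counts and ratios per group,
#'   `odds_ratio`, `p_value`, `q_value`, `significant` (q < 0.05).
#' @export
functional_enrichment <- function(presence, signature_groups) {
  case_ids <- names(signature_groups)[signature_groups == "case_enriched"]
  ctrl_ids <- names(signature_groups)[signature_groups == "control_enriched"]
  assert_that(length(case_ids) > 0 && length(ctrl_ids) > 0,
              "both signature groups must be nonempty")
  assert_that(all(c(case_ids, ctrl_ids) %in% colnames(presence)),
              "presence matrix is missing signature vOTUs")
  pm <- presence[, c(case_ids, ctrl_ids), drop = FALSE] > 0
  rows <- purrr::map(rownames(pm), function(f) {
    a <- sum(pm[f, case_ids]); b <- length(case_ids) - a
    c_ <- sum(pm[f, ctrl_ids]); d <- length(ctrl_ids) - c_
    ft <- suppressWarnings(fisher_exact_2x2(matrix(c(a, b, c_, d), 2,
                                                   byrow = TRUE)))
    tibble::tibble(function_id = f,
                   count_case_votus = a, count_control_votus = c_,
                   n_case_votus = length(case_ids),
                   n_control_votus = length(ctrl_ids),
                   occurrence_case = a / length(case_ids),
                   occurrence_control = c_ / length(ctrl_ids),
                   odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(q_value = bh_adjust(.data$p_value),
                  significant = .data$q_value < 0.05)
}
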
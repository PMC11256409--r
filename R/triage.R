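#' Viral contig triage
#'
#' Classify assembled contigs as viral or not from a table of per-contig
#' evidence: CheckV-style viral/host gene counts, a DeepVirFinder-style score
#' and p-value, a VIBRANT-style boolean call, the count of bacterial universal
#' single-copy orthologs (BUSCOs) among predicted genes, and CheckV-style
#' completeness/contamination estimates.
#'
#' Rules are applied in a fixed order; the first disqualifying rule decides
#' the verdict:
#' \enumerate{
#'   \item length screen: only contigs strictly longer than `min_length`
#'     (default 2000 bp) are considered (`too_short` otherwise);
#'   \item host-like exclusion: contigs with more than 10 host genes, that
#'     number also exceeding five times the viral gene count, are excluded
#'     (`excluded_hostlike`);
#'   \item candidate call: a contig is a viral candidate if it has more viral
#'     than host genes, or a DeepVirFinder score > 0.90 with p < 0.01, or a
#'     positive VIBRANT call; contigs failing all three are `nonviral`;
#'   \item contamination filter: candidates whose BUSCO ratio
#'     (`busco_count / total_gene_count`) is at least 5% are removed
#'     (`rejected_busco`);
#'   \item completeness filter: surviving candidates require estimated
#'     completeness strictly exceeding 50% (`rejected_completeness`),
#'     otherwise the verdict is `viral`.
#' }
#'
#' @param features A data frame with columns `contig_id`, `length`,
#'   `viral_gene_count`, `host_gene_count`, `total_gene_count`, `dvf_score`,
#'   `dvf_pvalue`, `vibrant_viral`, `busco_count`, `completeness`,
#'   `contamination`.
#' @param min_length Minimum contig length in bp, exclusive. Default 2000.
#' @param hostlike_conjunction If `TRUE` (default) the host-like exclusion
#'   requires both conditions (host genes > 10 AND host genes > 5x viral
#'   genes); if `FALSE` either condition alone excludes.
#' @return A tibble with one row per contig: `contig_id`, `verdict` (one of
#'   `viral`, `too_short`, `excluded_hostlike`, `nonviral`, `rejected_busco`,
#'   `rejected_completeness`) and `fired_rules` (semicolon-joined tags of the
#'   rules that determined or supported the verdict; empty only for
#'   `nonviral`).
#' @examples
#' feats <- tibble::tibble(
#'   contig_id = c("c1", "c2"), length = c(5000, 1500),
#'   viral_gene_count = c(8, 1), host_gene_count = c(2, 0),
#'   total_gene_count = c(12, 2), dvf_score = c(0.5, 0.99),
#'   dvf_pvalue = c(0.5, 0.001), vibrant_viral = c(FALSE, TRUE),
#'   busco_count = c(0, 0), completeness = c(80, 90), contamination = c(0, 0)
#' )
#' triage_contigs(feats)
#' @export
triage_contigs <- function(features, min_length = 2000,
                           hostlike_conjunction = TRUE) {
  assert_that(is.data.frame(features) && nrow(features) > 0,
              "`features` must be a nonempty data frame")
  required <- c("contig_id", "length", "viral_gene_count", "host_gene_count",
                "total_gene_count", "dvf_score", "dvf_pvalue", "vibrant_viral",
                "busco_count", "completeness", "contamination")
  missing <- setdiff(required, names(features))
  assert_that(length(missing) == 0,
              paste0("`features` is missing columns: ",
                     paste(missing, collapse = ", ")))
  dup <- features$contig_id[duplicated(features$contig_id)]
  assert_that(length(dup) == 0,
              paste0("duplicate contig_id: ", paste(unique(dup), collapse = ", ")))

  decide <- function(row) {
    if (!screen_length(row$length, min_length)) {
      return(list(verdict = "too_short", rules = "length_screen"))
    }
    if (hostlike_exclusion(row$viral_gene_count, row$host_gene_count,
                           conjunction = hostlike_conjunction)) {
      return(list(verdict = "excluded_hostlike", rules = "hostlike_exclusion"))
    }
    cand <- is_candidate_viral(row)
    if (!cand$candidate) {
      return(list(verdict = "nonviral", rules = character(0)))
    }
    if (row$total_gene_count >= 1 &&
        busco_ratio(row$busco_count, row$total_gene_count) >= 0.05) {
      return(list(verdict = "rejected_busco",
                  rules = c(cand$fired_rules, "busco_ratio")))
    }
    if (!(row$completeness > 50)) {
      return(list(verdict = "rejected_completeness",
                  rules = c(cand$fired_rules, "completeness_filter")))
    }
    list(verdict = "viral", rules = cand$fired_rules)
  }

  rows <- purrr::map(seq_len(nrow(features)), function(i) {
    d <- decide(features[i, , drop = FALSE])
    tibble::tibble(contig_id = features$contig_id[i],
                   verdict = d$verdict,
                   fired_rules = paste(d$rules, collapse = ";"))
  })
  dplyr::bind_rows(rows)
}

#' Contig length screen
#'
#' @param length Contig length in bp.
#' @param min_length Exclusive threshold (default 2000 bp).
#' @return `TRUE` iff `length` strictly exceeds `min_length`.
#' @export
screen_length <- function(length, min_length = 2000) {
  assert_that(all(length >= 0), "`length` must be nonnegative")
  length > min_length
}

#' Host-like contig exclusion
#'
#' Excludes contigs carrying more than ten host genes when that count also
#' exceeds five times the viral gene count (CheckV-style prescreen).
#'
#' @param viral_gene_count,host_gene_count Nonnegative gene counts.
#' @param conjunction Require both conditions (default) or either one.
#' @return `TRUE` if the contig should be excluded as host-like.
#' @export
hostlike_exclusion <- function(viral_gene_count, host_gene_count,
                               conjunction = TRUE) {
  assert_that(all(viral_gene_count >= 0) && all(host_gene_count >= 0),
              "gene counts must be nonnegative")
  a <- host_gene_count > 10
  b <- host_gene_count > 5 * viral_gene_count
  if (conjunction) a & b else a | b
}

#' Candidate viral call from combined detector evidence
#'
#' A contig is a viral candidate if any of three criteria holds: (1) more
#' viral than host genes; (2) DeepVirFinder-style score > 0.90 with
#' p-value < 0.01; (3) a positive VIBRANT-style call.
#'
#' @param features A one-row data frame (or list) with fields
#'   `viral_gene_count`, `host_gene_count`, `dvf_score`, `dvf_pvalue`,
#'   `vibrant_viral`.
#' @return A list with `candidate` (logical) and `fired_rules` (character
#'   vector among `gene_rule`, `dvf_rule`, `vibrant_rule`).
#' @export
is_candidate_viral <- function(features) {
  fired <- character(0)
  if (features$viral_gene_count > features$host_gene_count) {
    fired <- c(fired, "gene_rule")
  }
  if (features$dvf_score > 0.90 && features$dvf_pvalue < 0.01) {
    fired <- c(fired, "dvf_rule")
  }
  if (isTRUE(features$vibrant_viral)) fired <- c(fired, "vibrant_rule")
  list(candidate = length(fired) > 0, fired_rules = fired)
}

#' BUSCO contamination ratio
#'
#' Fraction of predicted genes matching bacterial universal single-copy
#' orthologs; values of 5% or more mark a candidate as bacterial
#' contamination.
#'
#' @param busco_count,total_gene_count Counts; `total_gene_count` must be at
#'   least 1.
#' @return `busco_count / total_gene_count`, in \[0, 1\].
#' @export
busco_ratio <- function(busco_count, total_gene_count) {
  assert_that(all(total_gene_count >= 1), "no predicted genes")
  assert_that(all(busco_count <= total_gene_count),
              "busco_count cannot exceed total_gene_count")
  busco_count / total_gene_count
}
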
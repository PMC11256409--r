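#' Pairwise similarity from alignment segments
#'
#' Summarise the (possibly fragmented) alignment between two sequences into a
#' single identity/coverage pair, as used by the 95%/70% vOTU clustering
#' criterion. Coverage is computed on the shorter of the two sequences: the
#' aligned segments are projected onto it, overlapping segments are merged,
#' and the union length is divided by the shorter length. Identity is the
#' alignment-length-weighted mean of the per-segment percent identities,
#' weighted by the pre-merge segment lengths.
#'
#' @param segments A data frame of alignment segments between one ordered
#'   sequence pair, with 1-based inclusive columns `q_start`, `q_end`,
#'   `s_start`, `s_end` and `percent_identity`. Zero rows are allowed.
#' @param len_query,len_subject Sequence lengths in bp.
#' @return A list with `identity` (percent) and `coverage` (fraction of the
#'   shorter sequence covered by the merged alignment). `(0, 0)` when there
#'   are no segments.
#' @examples
#' segs <- tibble::tibble(q_start = c(1, 301), q_end = c(400, 700),
#'                        s_start = c(1, 301), s_end = c(400, 700),
#'                        percent_identity = c(97, 96))
#' pair_similarity(segs, len_query = 1000, len_subject = 5000)
#' @export
pair_similarity <- function(segments, len_query, len_subject) {
  assert_that(len_query >= 1 && len_subject >= 1,
              "sequence lengths must be positive")
  if (is.null(segments) || nrow(segments) == 0) {
    return(list(identity = 0, coverage = 0))
  }
  on_query <- len_query <= len_subject
  starts <- if (on_query) segments$q_start else pmin(segments$s_start, segments$s_end)
  ends <- if (on_query) segments$q_end else pmax(segments$s_start, segments$s_end)
  assert_that(all(starts <= ends), "segment start must not exceed end")
  seg_len <- ends - starts + 1

  ord <- order(starts, ends)
  merged <- 0
  cur_s <- starts[ord[1]]
  cur_e <- ends[ord[1]]
  for (i in ord[-1]) {
    if (starts[i] <= cur_e + 1) {
      cur_e <- max(cur_e, ends[i])
    } else {
      merged <- merged + (cur_e - cur_s + 1)
      cur_s <- starts[i]
      cur_e <- ends[i]
    }
  }
  merged <- merged + (cur_e - cur_s + 1)
  shorter <- min(len_query, len_subject)
  list(
    identity = sum(segments$percent_identity * seg_len) / sum(seg_len),
    coverage = merged / shorter
  )
}

#' Greedy centroid clustering of viral genomes into vOTUs
#'
#' Sequences are visited in order of decreasing length (ties broken by
#' lexicographic id). Each sequence joins the first existing cluster whose
#' centroid it matches at `id_threshold` percent identity or more over
#' `cov_threshold` coverage or more; otherwise it founds a new cluster. The
#' centroid — by construction the longest member — is the cluster's
#' representative (the vOTU reference sequence).
#'
#' @param lengths Named numeric vector (or two-column data frame `id`,
#'   `length`) of sequence lengths in bp.
#' @param similarities Data frame with columns `query_id`, `subject_id`,
#'   `identity` (percent) and `coverage` (fraction). Treated as symmetric;
#'   when both orientations are present the elementwise maximum is used.
#' @param id_threshold Percent identity threshold, inclusive. Default 95.
#' @param cov_threshold Coverage threshold, inclusive fraction. Default 0.70.
#' @param strict If `TRUE` use strict `>` comparisons instead of `>=`.
#' @return A tibble with columns `representative_id`, `member_id`, `length`.
#' @export
cluster_votus <- function(lengths, similarities,
                          id_threshold = 95, cov_threshold = 0.70,
                          strict = FALSE) {
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$id)
  }
  assert_that(all(lengths > 0), "sequence lengths must be positive")
  ids <- names(lengths)
  assert_that(!is.null(ids) && !anyDuplicated(ids),
              "`lengths` must be uniquely named by sequence id")
  if (is.null(similarities)) {
    similarities <- tibble::tibble(query_id = character(),
                                   subject_id = character(),
                                   identity = numeric(), coverage = numeric())
  }
  unknown <- setdiff(unique(c(similarities$query_id, similarities$subject_id)),
                     ids)
  assert_that(length(unknown) == 0,
              paste0("unknown id in similarity table: ",
                     paste(unknown, collapse = ", ")))

  # Symmetrise by max over the two orientations.
  sym <- dplyr::bind_rows(
    similarities[, c("query_id", "subject_id", "identity", "coverage")],
    tibble::tibble(query_id = similarities$subject_id,
                   subject_id = similarities$query_id,
                   identity = similarities$identity,
                   coverage = similarities$coverage)
  ) |>
    dplyr::filter(.data$query_id != .data$subject_id) |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::summarise(identity = max(.data$identity),
                     coverage = max(.data$coverage), .groups = "drop")
  key <- paste(sym$query_id, sym$subject_id, sep = "\r")
  sim_id <- setNames(sym$identity, key)
  sim_cov <- setNames(sym$coverage, key)

  passes <- function(a, b) {
    k <- paste(a, b, sep = "\r")
    idn <- unname(sim_id[k])
    if (is.na(idn)) return(FALSE)
    cv <- unname(sim_cov[k])
    if (strict) idn > id_threshold && cv > cov_threshold
    else idn >= id_threshold && cv >= cov_threshold
  }

  ord <- ids[order(-lengths, ids)]
  centroids <- character(0)
  assignment <- character(length(ord))
  names(assignment) <- ord
  for (s in ord) {
    placed <- FALSE
    for (cen in centroids) {
      if (passes(s, cen)) {
        assignment[[s]] <- cen
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, s)
      assignment[[s]] <- s
    }
  }
  tibble::tibble(
    representative_id = unname(assignment),
    member_id = names(assignment),
    length = unname(lengths[names(assignment)])
  ) |>
    dplyr::arrange(.data$representative_id, dplyr::desc(.data$length),
                   .data$member_id)
}

#' Restrict a catalog to clusters anchored by study sequences
#'
#' When study genomes are co-clustered with an external reference catalog,
#' only clusters containing at least one genome identified in the study are
#' retained; clusters made up entirely of external sequences are dropped.
#'
#' @param catalog Cluster tibble as returned by [cluster_votus()].
#' @param sources Named character vector mapping every `member_id` to
#'   `"study"` or `"external"`.
#' @return The filtered cluster tibble with an added `source` column.
#' @export
integrate_external <- function(catalog, sources) {
  missing <- setdiff(catalog$member_id, names(sources))
  assert_that(length(missing) == 0,
              paste0("missing source label for: ",
                     paste(missing, collapse = ", ")))
  assert_that(all(sources %in% c("study", "external")),
              "sources must be 'study' or 'external'")
  catalog |>
    dplyr::mutate(source = unname(sources[.data$member_id])) |>
    dplyr::group_by(.data$representative_id) |>
    dplyr::filter(any(.data$source == "study")) |>
    dplyr::ungroup()
}

#' Genome quality tier from completeness and contamination
#'
#' @param completeness,contamination Percentages in \[0, 100\].
#' @return A tibble with `tier` (`complete` at 100% completeness, `high` at
#'   90% or more, `medium` at 50% or more, `low` otherwise) and
#'   `low_contamination` (`TRUE` when contamination < 10%). Vectorised.
#' @export
quality_tier <- function(completeness, contamination) {
  assert_that(all(completeness >= 0 & completeness <= 100) &&
                all(contamination >= 0 & contamination <= 100),
              "completeness and contamination must be in [0, 100]")
  tier <- dplyr::case_when(
    completeness == 100 ~ "complete",
    completeness >= 90 ~ "high",
    completeness >= 50 ~ "medium",
    TRUE ~ "low"
  )
  tibble::tibble(tier = tier, low_contamination = contamination < 10)
}
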
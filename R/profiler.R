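#' Trimmed mean sequencing depth
#'
#' Robust per-genome depth estimate: base positions (including zero-depth
#' positions) are sorted by depth, the lowest and highest 10% of positions
#' are discarded, and the arithmetic mean of the remainder is returned. The
#' trim count per side is `floor(0.1 * L)`, so vectors shorter than 10
#' positions are not trimmed at all.
#'
#' @param depths Numeric vector of nonnegative per-base depths, one entry per
#'   base position of the genome.
#' @return The trimmed mean depth (reads/bp).
#' @examples
#' trimmed_depth(0:9) # drops the 0 and the 9 -> mean(1:8) = 4.5
#' @export
trimmed_depth <- function(depths) {
  assert_that(length(depths) >= 1, "empty depth vector")
  assert_that(all(depths >= 0), "depths must be nonnegative")
  l <- length(depths)
  k <- floor(0.1 * l)
  s <- sort.int(depths, method = "radix")
  mean(s[(k + 1):(l - k)])
}

#' Zero out depths lacking classified-read confirmation
#'
#' Sequencing depth estimated from read alignment can be inflated by
#' mismapped reads; a vOTU's depth is therefore set to zero in any sample
#' where an independent read classifier assigned it no reads at all.
#'
#' @param depth_by_votu Named numeric vector of per-vOTU depths for one
#'   sample.
#' @param confirmed_counts Named numeric vector of classified-read counts,
#'   over the same vOTU ids.
#' @return `depth_by_votu` with unconfirmed entries set to 0.
#' @export
apply_confirmation <- function(depth_by_votu, confirmed_counts) {
  missing <- setdiff(names(depth_by_votu), names(confirmed_counts))
  extra <- setdiff(names(confirmed_counts), names(depth_by_votu))
  assert_that(length(missing) == 0 && length(extra) == 0,
              paste0("vOTU key mismatch; missing counts for: ",
                     paste(missing, collapse = ", "),
                     if (length(extra)) paste0("; extra counts for: ",
                                               paste(extra, collapse = ", "))
                     else ""))
  assert_that(all(confirmed_counts >= 0), "counts must be nonnegative")
  out <- depth_by_votu
  out[confirmed_counts[names(out)] == 0] <- 0
  out
}

#' Relative abundance from per-vOTU depths
#'
#' @param depth_by_votu Named nonnegative numeric vector of depths for one
#'   sample.
#' @return Depths divided by their sum; an all-zero input is returned
#'   unchanged (no viral signal in the sample).
#' @export
relative_abundance <- function(depth_by_votu) {
  assert_that(all(depth_by_votu >= 0), "negative depth")
  total <- sum(depth_by_votu)
  if (total == 0) return(depth_by_votu)
  depth_by_votu / total
}

#' Build a sample-by-vOTU relative abundance profile
#'
#' Applies the three-step abundance model to a depth store: (1) trimmed mean
#' depth per (sample, vOTU); (2) confirmation zeroing by classified-read
#' counts; (3) per-sample renormalisation to relative abundances.
#'
#' @param depth_store Long tibble with columns `sample_id`, `votu_id` and a
#'   list-column `depths` of per-base depth vectors, or precomputed numeric
#'   `depth` column.
#' @param confirm_counts Tibble with columns `sample_id`, `votu_id`, `count`.
#' @return A long tibble `sample_id`, `votu_id`, `abundance`; each sample's
#'   abundances sum to 1 or are all zero.
#' @export
profile_abundance <- function(depth_store, confirm_counts) {
  assert_that(all(c("sample_id", "votu_id") %in% names(depth_store)),
              "`depth_store` needs sample_id and votu_id columns")
  if ("depths" %in% names(depth_store)) {
    depth_store <- depth_store |>
      dplyr::mutate(depth = purrr::map_dbl(.data$depths, trimmed_depth)) |>
      dplyr::select(-"depths")
  }
  assert_that("depth" %in% names(depth_store),
              "`depth_store` needs a depths list-column or a depth column")
  cc <- confirm_counts |>
    dplyr::select("sample_id", "votu_id", "count")
  joined <- dplyr::left_join(depth_store, cc,
                             by = c("sample_id", "votu_id"))
  assert_that(!anyNA(joined$count),
              "confirm_counts is missing (sample, vOTU) pairs")
  joined |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      depth = ifelse(.data$count == 0, 0, .data$depth),
      abundance = if (sum(.data$depth) == 0) .data$depth
                  else .data$depth / sum(.data$depth)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "votu_id", "abundance")
}

#' Aggregate a vOTU profile to family level
#'
#' @param profile Long tibble `sample_id`, `votu_id`, `abundance`.
#' @param family_map Named character vector mapping every vOTU id to a family
#'   name (use `"unclassified"` for unassigned vOTUs).
#' @return Long tibble `sample_id`, `family`, `abundance` with per-sample row
#'   sums preserved.
#' @export
aggregate_family <- function(profile, family_map) {
  unmapped <- setdiff(unique(profile$votu_id), names(family_map))
  assert_that(length(unmapped) == 0,
              paste0("unmapped vOTUs: ", paste(unmapped, collapse = ", ")))
  profile |>
    dplyr::mutate(family = unname(family_map[.data$votu_id])) |>
    dplyr::group_by(.data$sample_id, .data$family) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
}

#' Virus-to-bacterium cell-count ratio
#'
#' Genome-length-normalised read counts approximate particle/cell counts:
#' `cell_count = mapped_reads / genome_length`. The ratio is the summed viral
#' cell count divided by the summed bacterial cell count.
#'
#' @param read_counts,genome_lengths Numeric vectors per entity.
#' @param kingdom_labels Character vector in `{"virus", "bacterium"}`.
#' @return The virus-to-bacterium ratio; `Inf` with a warning when there are
#'   no bacterial reads.
#' @export
virus_bacterium_ratio <- function(read_counts, genome_lengths, kingdom_labels) {
  assert_that(all(genome_lengths > 0), "genome lengths must be positive")
  assert_that(all(kingdom_labels %in% c("virus", "bacterium")),
              "kingdom labels must be 'virus' or 'bacterium'")
  cells <- read_counts / genome_lengths
  v <- sum(cells[kingdom_labels == "virus"])
  b <- sum(cells[kingdom_labels == "bacterium"])
  if (b == 0) {
    warn("no bacterial signal; virus-to-bacterium ratio is undefined")
    return(Inf)
  }
  v / b
}

#' Convert a long profile to a sample-by-vOTU matrix
#'
#' @param profile Long tibble `sample_id`, `votu_id`, `abundance`.
#' @return Numeric matrix, rows = samples, columns = vOTUs.
#' @export
profile_matrix <- function(profile) {
  wide <- profile |>
    tidyr::pivot_wider(names_from = "votu_id", values_from = "abundance",
                       values_fill = 0) |>
    dplyr::arrange(.data$sample_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m[, order(colnames(m)), drop = FALSE]
}
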
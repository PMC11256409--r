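#' Built-in family-to-kingdom lookup
#'
#' Static classification of the viral families handled by the annotation
#' module into eukaryote-infecting and prokaryote-infecting (phage) groups,
#' used to split diversity analyses into eukaryotic and prokaryotic viromes.
#'
#' @return A tibble with columns `family` and `kingdom`.
#' @export
family_kingdoms <- function() {
  tibble::tibble(
    family = c("Siphoviridae", "Myoviridae", "Microviridae", "Podoviridae",
               "crAss-like", "Quimbyviridae", "Inoviridae", "Salasmaviridae",
               "Autographiviridae", "Gratiaviridae",
               "Anelloviridae", "Adenoviridae", "Retroviridae",
               "Genomoviridae", "Hepadnaviridae"),
    kingdom = c(rep("prokaryotic", 10), rep("eukaryotic", 5))
  )
}

kingdom_of <- function(family) {
  lut <- family_kingdoms()
  k <- lut$kingdom[match(family, lut$family)]
  k[is.na(k) | family == "unclassified"] <- "unknown"
  k
}

#' Filter protein-vs-reference hits
#'
#' Applies the alignment thresholds used for taxonomic annotation searches
#' (diamond-style, all inclusive): identity >= 30%, query coverage >= 50%,
#' subject coverage >= 50%, bit score >= 50.
#'
#' @param hits Data frame with columns `percent_identity`, `query_coverage`,
#'   `subject_coverage`, `bit_score` (plus any id columns, preserved).
#' @param min_identity,min_query_cover,min_subject_cover,min_score
#'   Thresholds, all inclusive.
#' @return The retained rows.
#' @export
filter_hits <- function(hits, min_identity = 30, min_query_cover = 50,
                        min_subject_cover = 50, min_score = 50) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::filter(.data$percent_identity >= min_identity,
                  .data$query_coverage >= min_query_cover,
                  .data$subject_coverage >= min_subject_cover,
                  .data$bit_score >= min_score)
}

#' Family assignment by protein voting
#'
#' A vOTU is assigned to the viral family gathering the most protein matches,
#' subject to a size-dependent quorum: genomes with fewer than 30 predicted
#' genes require strictly more than one fifth of their proteins matched to
#' that family; genomes with 30 or more genes require at least 10 matched
#' proteins. Ties for the best family yield `unclassified`.
#'
#' @param total_genes Number of predicted protein-coding genes of the vOTU.
#' @param family_counts Named numeric vector of distinct-protein match counts
#'   per candidate family (may be empty).
#' @return A single family name or `"unclassified"`.
#' @export
assign_family <- function(total_genes, family_counts) {
  if (total_genes == 0) {
    warn("vOTU has no predicted genes; family is unclassified")
    return("unclassified")
  }
  if (length(family_counts) == 0) return("unclassified")
  assert_that(all(family_counts <= total_genes),
              "family match counts cannot exceed total gene count")
  best <- max(family_counts)
  if (sum(family_counts == best) > 1) return("unclassified")
  fam <- names(family_counts)[which.max(family_counts)]
  ok <- if (total_genes < 30) best > total_genes / 5 else best >= 10
  if (ok) fam else "unclassified"
}

#' Prokaryotic host assignment from spacer and alignment evidence
#'
#' Two evidence channels link a virus to a candidate host genome: a CRISPR
#' spacer from the host matching the viral genome with BLASTn bit score of 45
#' or greater, or a direct genome alignment at >= 90% nucleotide identity
#' covering >= 30% of the viral genome. A vOTU may collect several hosts.
#'
#' @param evidence Data frame with columns `votu_id`, `host_genome_id`,
#'   `kind` (`"crispr_spacer"` or `"genome_alignment"`), `bit_score` (spacer
#'   rows), `percent_identity` and `viral_coverage` (alignment rows; coverage
#'   as a fraction).
#' @param min_spacer_score,min_aln_identity,min_aln_coverage Thresholds.
#' @return A tibble `votu_id`, `host_genome_id`, `kind` of accepted links,
#'   deduplicated.
#' @export
assign_hosts <- function(evidence, min_spacer_score = 45,
                         min_aln_identity = 90, min_aln_coverage = 0.30) {
  if (nrow(evidence) == 0) {
    return(tibble::tibble(votu_id = character(), host_genome_id = character(),
                          kind = character()))
  }
  assert_that(all(evidence$kind %in% c("crispr_spacer", "genome_alignment")),
              "evidence kind must be crispr_spacer or genome_alignment")
  sp <- evidence |>
    dplyr::filter(.data$kind == "crispr_spacer")
  if (nrow(sp) > 0) {
    assert_that(!anyNA(sp$bit_score),
                "crispr_spacer evidence rows require bit_score")
  }
  al <- evidence |>
    dplyr::filter(.data$kind == "genome_alignment")
  if (nrow(al) > 0) {
    assert_that(!anyNA(al$percent_identity) && !anyNA(al$viral_coverage),
                "genome_alignment rows require percent_identity and viral_coverage")
  }
  kept <- dplyr::bind_rows(
    dplyr::filter(sp, .data$bit_score >= min_spacer_score),
    dplyr::filter(al, .data$percent_identity >= min_aln_identity,
                  .data$viral_coverage >= min_aln_coverage)
  )
  kept |>
    dplyr::distinct(.data$votu_id, .data$host_genome_id, .data$kind)
}

#' Annotate a vOTU catalog
#'
#' Combines protein-hit filtering, family voting, kingdom lookup and host
#' assignment into one annotation table.
#'
#' @param protein_hits Data frame of protein hits with columns `votu_id`,
#'   `protein_id`, `target_family`, `percent_identity`, `query_coverage`,
#'   `subject_coverage`, `bit_score`.
#' @param gene_counts Named numeric vector of total predicted genes per vOTU.
#' @param host_evidence Optional host evidence table (see [assign_hosts()]).
#' @param votu_ids Character vector of all vOTUs to annotate (defaults to the
#'   names of `gene_counts`).
#' @return A tibble `votu_id`, `family`, `kingdom`, `hosts` (semicolon-joined
#'   host genome ids, empty string when none).
#' @export
annotate_votus <- function(protein_hits, gene_counts, host_evidence = NULL,
                           votu_ids = names(gene_counts)) {
  kept <- filter_hits(protein_hits)
  fam <- purrr::map_chr(votu_ids, function(v) {
    h <- kept[kept$votu_id == v, , drop = FALSE]
    counts <- h |>
      dplyr::distinct(.data$protein_id, .data$target_family) |>
      dplyr::count(.data$target_family)
    assign_family(gene_counts[[v]] %||% 0,
                  setNames(counts$n, counts$target_family))
  })
  hosts <- if (is.null(host_evidence)) {
    tibble::tibble(votu_id = character(), host_genome_id = character())
  } else {
    assign_hosts(host_evidence)
  }
  host_str <- hosts |>
    dplyr::group_by(.data$votu_id) |>
    dplyr::summarise(hosts = paste(sort(unique(.data$host_genome_id)),
                                   collapse = ";"))
  tibble::tibble(votu_id = votu_ids, family = fam,
                 kingdom = kingdom_of(fam)) |>
    dplyr::left_join(host_str, by = "votu_id") |>
    dplyr::mutate(hosts = dplyr::coalesce(.data$hosts, ""))
}
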
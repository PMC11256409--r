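# Readers/writers for the pipeline's on-disk formats. All tables are TSV
# with a header row, UTF-8, LF line endings, '.' for missing values;
# coordinates in files are 1-based inclusive.

write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path, na = ".", eol = "\n")
  invisible(path)
}

read_tsv_file <- function(path, col_types = NULL) {
  readr::read_tsv(path, na = ".", col_types = col_types %||% readr::cols(),
                  progress = FALSE)
}

#' Write FASTA sequences
#'
#' Unwrapped single-line sequences; ids are written as given.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  assert_that(!is.null(names(seqs)), "sequences must be named")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", seqs), con, sep = "\n")
  invisible(path)
}

#' Read FASTA sequences
#'
#' Accepts wrapped or unwrapped records; nucleotides are upper-cased and ids
#' are cut at the first whitespace.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  assert_that(any(hdr) && hdr[1], "not a FASTA file")
  idx <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  setNames(unname(seqs), ids)
}

#' Serialise a synthetic study to a directory
#'
#' Writes `genomes.fasta`, `contig_features.tsv`, `samples.tsv`,
#' `truth.tsv`, `confirm_counts.tsv`, `alignments.tsv`, `hits_protein.tsv`,
#' `hits_spacer.tsv`, `hits_genome.tsv` and per-(sample, vOTU) depth files
#' `depth/<sample>/<votu>.tsv` (columns: 1-based `position`, `depth`).
#'
#' @param study A `virosig_study`.
#' @param dir Output directory (created if needed).
#' @param write_depths Write the (possibly numerous) per-base depth files.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, write_depths = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(study$genomes, file.path(dir, "genomes.fasta"))
  write_tsv_file(study$contig_features, file.path(dir, "contig_features.tsv"))
  write_tsv_file(study$samples, file.path(dir, "samples.tsv"))
  write_tsv_file(study$truth, file.path(dir, "truth.tsv"))
  write_tsv_file(study$alignments, file.path(dir, "alignments.tsv"))
  write_tsv_file(study$protein_hits, file.path(dir, "hits_protein.tsv"))
  write_tsv_file(study$spacer_hits, file.path(dir, "hits_spacer.tsv"))
  write_tsv_file(study$genome_aln_hits, file.path(dir, "hits_genome.tsv"))
  if (!is.null(study$confirm_counts)) {
    write_tsv_file(study$confirm_counts, file.path(dir, "confirm_counts.tsv"))
  }
  if (write_depths && !is.null(study$depth_store)) {
    for (i in seq_len(nrow(study$depth_store))) {
      sid <- study$depth_store$sample_id[i]
      vid <- study$depth_store$votu_id[i]
      d <- file.path(dir, "depth", sid)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      dv <- study$depth_store$depths[[i]]
      write_tsv_file(tibble::tibble(position = seq_along(dv), depth = dv),
                     file.path(d, paste0(vid, ".tsv")))
    }
  }
  invisible(dir)
}

#' Read a serialised study back from a directory
#'
#' @param dir Directory written by [write_study()].
#' @param read_depths Also read the per-base depth files.
#' @return A list with the same tabular components as a `virosig_study`.
#' @export
read_study <- function(dir, read_depths = TRUE) {
  out <- list(
    genomes = read_fasta(file.path(dir, "genomes.fasta")),
    contig_features = read_tsv_file(file.path(dir, "contig_features.tsv")),
    samples = read_tsv_file(file.path(dir, "samples.tsv")),
    truth = read_tsv_file(file.path(dir, "truth.tsv")),
    alignments = read_tsv_file(file.path(dir, "alignments.tsv")),
    protein_hits = read_tsv_file(file.path(dir, "hits_protein.tsv")),
    spacer_hits = read_tsv_file(file.path(dir, "hits_spacer.tsv")),
    genome_aln_hits = read_tsv_file(file.path(dir, "hits_genome.tsv"))
  )
  cc <- file.path(dir, "confirm_counts.tsv")
  if (file.exists(cc)) out$confirm_counts <- read_tsv_file(cc)
  depth_dir <- file.path(dir, "depth")
  if (read_depths && dir.exists(depth_dir)) {
    rows <- list()
    for (sid in sort(list.dirs(depth_dir, recursive = FALSE,
                               full.names = FALSE))) {
      for (f in sort(list.files(file.path(depth_dir, sid), "\\.tsv$"))) {
        tab <- read_tsv_file(file.path(depth_dir, sid, f))
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = sid,
          votu_id = sub("\\.tsv$", "", f),
          depths = list(as.numeric(tab$depth))
        )
      }
    }
    out$depth_store <- dplyr::bind_rows(rows)
  }
  out
}
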
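#' Synthetic study configuration
#'
#' Bundles and validates all parameters of the synthetic cohort generator.
#' The generator emulates the intermediate files a gut-virome case-control
#' study produces after read processing: per-contig detector evidence, per
#' (sample, vOTU) per-base depth vectors, classified-read confirmation
#' counts, protein/spacer/genome hit tables and a sample sheet, together
#' with a ground-truth table of planted case- and control-enriched vOTUs.
#'
#' @param n_case,n_control Subjects per group; each subject contributes one
#'   VLP and one bulk sample sharing a latent viral community.
#' @param n_votus Number of vOTUs in the community.
#' @param n_planted_case_enriched,n_planted_control_enriched Numbers of
#'   vOTUs whose abundance is multiplied by `effect_fold` in cases
#'   (respectively controls).
#' @param effect_fold Multiplicative group effect (>= 1; 1 gives a null
#'   cohort in which planted labels are still recorded).
#' @param genome_length_range Two-element bp interval for vOTU genome
#'   lengths.
#' @param mean_depth Average per-base sequencing depth (reads/bp) a vOTU of
#'   average abundance receives.
#' @param vlp_bias_families Named numeric vector of multiplicative capture
#'   factors applied to whole families in VLP samples before compositional
#'   closure, emulating the VLP enrichment bias.
#' @param dropout_rate Probability that a truly absent vOTU nevertheless
#'   receives spurious low read depth in a sample (removed downstream by the
#'   classified-read confirmation step).
#' @param carriage_prob Probability that a subject carries any given vOTU;
#'   non-carriers have true abundance 0. The default of 1 matches the base
#'   log-normal-then-closed abundance model (every vOTU present in every
#'   subject); lower it to study sparser communities, in which the planted
#'   effect is harder to recover.
#' @param seed Integer master seed; fans out to per-component child seeds by
#'   stable hashing, so generation is independent of evaluation order.
#' @return A validated list of class `virosig_config`.
#' @export
sim_config <- function(n_case = 30, n_control = 30, n_votus = 50,
                       n_planted_case_enriched = 10,
                       n_planted_control_enriched = 10,
                       effect_fold = 4,
                       genome_length_range = c(2000, 10000),
                       mean_depth = 10,
                       vlp_bias_families = c(Microviridae = 5, Myoviridae = 0.3),
                       dropout_rate = 0.02,
                       carriage_prob = 1,
                       seed = 1) {
  for (nm in c("n_case", "n_control", "n_votus", "n_planted_case_enriched",
               "n_planted_control_enriched")) {
    assert_that(is_count(get(nm)), paste0("`", nm, "` must be a count"))
  }
  assert_that(n_case >= 1 && n_control >= 1, "both groups need subjects")
  assert_that(n_planted_case_enriched + n_planted_control_enriched <= n_votus,
              "planted vOTUs cannot exceed n_votus")
  assert_that(is.numeric(effect_fold) && effect_fold >= 1,
              "`effect_fold` must be >= 1")
  assert_that(length(genome_length_range) == 2 &&
                genome_length_range[1] >= 1 &&
                genome_length_range[1] <= genome_length_range[2],
              "`genome_length_range` must be an increasing positive interval")
  assert_that(mean_depth >= 0, "`mean_depth` must be nonnegative")
  assert_that(dropout_rate >= 0 && dropout_rate <= 1,
              "`dropout_rate` must be a probability in [0, 1]")
  assert_that(carriage_prob >= 0 && carriage_prob <= 1,
              "`carriage_prob` must be a probability in [0, 1]")
  assert_that(is.numeric(seed) && length(seed) == 1 && seed == floor(seed),
              "`seed` must be an integer")
  structure(list(n_case = n_case, n_control = n_control, n_votus = n_votus,
                 n_planted_case_enriched = n_planted_case_enriched,
                 n_planted_control_enriched = n_planted_control_enriched,
                 effect_fold = effect_fold,
                 genome_length_range = genome_length_range,
                 mean_depth = mean_depth,
                 vlp_bias_families = vlp_bias_families,
                 dropout_rate = dropout_rate,
                 carriage_prob = carriage_prob,
                 seed = seed),
            class = "virosig_config")
}

# Family pool the generator samples vOTU taxonomy from, with rough gut-virome
# frequencies: tailed and Microviridae phages dominate, a sliver of
# eukaryotic viruses, and a block of dark-matter (unclassified) vOTUs.
synth_family_pool <- function() {
  tibble::tibble(
    family = c("Siphoviridae", "Myoviridae", "Microviridae", "Podoviridae",
               "crAss-like", "Quimbyviridae", "Anelloviridae", "unclassified"),
    weight = c(0.22, 0.14, 0.16, 0.08, 0.08, 0.04, 0.04, 0.24)
  )
}

synth_host_pool <- function() {
  c("Bacteroides_uniformis", "Prevotella_copri", "Faecalibacterium_prausnitzii",
    "Escherichia_coli", "Agathobaculum_butyriciproducens",
    "Roseburia_intestinalis", "Akkermansia_muciniphila",
    "Citrobacter_farmeri")
}

#' Simulate a per-base depth vector
#'
#' @param genome_length Genome length in bp (>= 1).
#' @param target_depth Mean depth in reads/bp (>= 0).
#' @param seed Integer seed.
#' @return Integer vector of length `genome_length`; entries i.i.d.
#'   Poisson(`target_depth`).
#' @export
generate_depth_vector <- function(genome_length, target_depth, seed) {
  assert_that(is_count(genome_length) && genome_length >= 1,
              "`genome_length` must be a positive integer")
  assert_that(target_depth >= 0, "`target_depth` must be nonnegative")
  with_seed(seed, rpois(genome_length, target_depth))
}

random_genome <- function(length, seed) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))
}

#' Generate a synthetic case-control virome cohort
#'
#' Draws a complete synthetic study from a [sim_config()]. Per-subject
#' latent vOTU abundances are log-normal(0, 1), zeroed for non-carried
#' vOTUs, multiplied by `effect_fold` for planted vOTUs in their favoured
#' group, and closed to relative abundances. Each subject contributes a VLP
#' sample (family-specific capture factors applied before re-closure) and a
#' bulk sample. Per-base depths are Poisson with mean proportional to sample
#' abundance times `mean_depth`; truly absent vOTUs occasionally receive
#' spurious low depth (rate `dropout_rate`) which carries a zero
#' classified-read confirmation count. Contig feature tables (with decoy
#' non-viral contigs), near-duplicate contigs with alignment records, and
#' protein/spacer/genome hit tables consistent with the planted taxonomy and
#' hosts are generated alongside.
#'
#' @param config A [sim_config()].
#' @param cohort_id Cohort label written into the sample sheet.
#' @param depths If `FALSE`, skip per-base depth and confirmation-count
#'   simulation (faster when only true abundances are needed).
#' @return An object of class `virosig_study`; see Details for components.
#' @details Components: `config`, `samples` (sample sheet), `truth`
#'   (planted status, family, kingdom, host, genome length per vOTU),
#'   `abundance` (true compositional sample x vOTU abundances, long),
#'   `depth_store`, `confirm_counts`, `contig_features`, `contig_truth`,
#'   `alignments`, `protein_hits`, `spacer_hits`, `genome_aln_hits`,
#'   `genomes` (named character vector of sequences).
#' @export
simulate_cohort <- function(config, cohort_id = "cohort1", depths = TRUE) {
  assert_that(inherits(config, "virosig_config"),
              "`config` must come from sim_config()")
  cfg <- config
  votu_ids <- sprintf("vOTU%03d", seq_len(cfg$n_votus))
  planted <- rep("null", cfg$n_votus)
  if (cfg$n_planted_case_enriched > 0) {
    planted[seq_len(cfg$n_planted_case_enriched)] <- "case_enriched"
  }
  if (cfg$n_planted_control_enriched > 0) {
    planted[cfg$n_planted_case_enriched +
              seq_len(cfg$n_planted_control_enriched)] <- "control_enriched"
  }

  # vOTU-level truth: family, kingdom, host, genome length.
  pool <- synth_family_pool()
  truth <- with_seed(child_seed(cfg$seed, "votus"), {
    fam <- sample(pool$family, cfg$n_votus, replace = TRUE, prob = pool$weight)
    kingdom <- kingdom_of(fam)
    host <- ifelse(kingdom == "prokaryotic",
                   sample(synth_host_pool(), cfg$n_votus, replace = TRUE),
                   NA_character_)
    len <- floor(runif(cfg$n_votus, cfg$genome_length_range[1],
                       cfg$genome_length_range[2] + 1))
    tibble::tibble(votu_id = votu_ids, planted = planted, family = fam,
                   kingdom = kingdom, host = host, genome_length = len)
  })

  subjects <- c(sprintf("case%03d", seq_len(cfg$n_case)),
                sprintf("ctrl%03d", seq_len(cfg$n_control)))
  groups <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  samples <- tidyr::expand_grid(
    subject_id = subjects, modality = c("vlp", "bulk")
  ) |>
    dplyr::mutate(
      group = rep(groups, each = 2),
      cohort = cohort_id,
      sample_id = paste(cohort_id, .data$subject_id, .data$modality, sep = "_")
    ) |>
    dplyr::select("sample_id", "subject_id", "group", "modality", "cohort")

  fold <- rep(1, cfg$n_votus)
  bias <- rep(1, cfg$n_votus)
  hit <- match(truth$family, names(cfg$vlp_bias_families))
  bias[!is.na(hit)] <- cfg$vlp_bias_families[hit[!is.na(hit)]]

  # Latent abundances per subject, then one closed composition per sample.
  abundance_rows <- purrr::map(seq_along(subjects), function(i) {
    subj <- subjects[i]
    latent <- with_seed(child_seed(cfg$seed, paste0("latent:", subj)), {
      carried <- rbinom(cfg$n_votus, 1, cfg$carriage_prob)
      exp(rnorm(cfg$n_votus, 0, 1)) * carried
    })
    eff <- ifelse(
      truth$planted == "case_enriched" & groups[i] == "case", cfg$effect_fold,
      ifelse(truth$planted == "control_enriched" & groups[i] == "control",
             cfg$effect_fold, 1)
    )
    latent <- latent * eff
    close <- function(x) if (sum(x) == 0) x else x / sum(x)
    tibble::tibble(
      subject_id = subj,
      votu_id = rep(votu_ids, 2),
      modality = rep(c("vlp", "bulk"), each = cfg$n_votus),
      abundance = c(close(latent * bias), close(latent))
    )
  })
  abundance <- dplyr::bind_rows(abundance_rows) |>
    dplyr::left_join(samples[, c("sample_id", "subject_id", "modality")],
                     by = c("subject_id", "modality")) |>
    dplyr::select("sample_id", "votu_id", "abundance")

  study <- list(config = cfg, cohort_id = cohort_id, samples = samples,
                truth = truth, abundance = abundance)

  if (depths) {
    glen <- setNames(truth$genome_length, votu_ids)
    depth_rows <- purrr::map(samples$sample_id, function(sid) {
      ab <- abundance$abundance[abundance$sample_id == sid]
      names(ab) <- abundance$votu_id[abundance$sample_id == sid]
      seed_s <- child_seed(cfg$seed, paste0("depth:", sid))
      with_seed(seed_s, {
        spurious <- ab == 0 & runif(cfg$n_votus) < cfg$dropout_rate
        target <- ab[votu_ids] * cfg$n_votus * cfg$mean_depth
        target[spurious[votu_ids]] <- 0.05 * cfg$mean_depth
        dvec <- lapply(votu_ids, function(v) {
          if (target[[v]] == 0) integer(glen[[v]])
          else rpois(glen[[v]], target[[v]])
        })
        counts <- vapply(votu_ids, function(v) {
          if (spurious[[v]] || target[[v]] == 0) 0L
          else rpois(1, target[[v]] * glen[[v]] / 150)
        }, integer(1))
        tibble::tibble(sample_id = sid, votu_id = votu_ids,
                       depths = dvec, count = counts)
      })
    }) |>
      dplyr::bind_rows()
    study$depth_store <- depth_rows[, c("sample_id", "votu_id", "depths")]
    study$confirm_counts <- depth_rows[, c("sample_id", "votu_id", "count")]
  }

  study <- c(study, synth_evidence_tables(cfg, truth))
  structure(study, class = "virosig_study")
}

# Contig features, duplicate contigs + alignments, and annotation hit tables
# consistent with the planted truth.
synth_evidence_tables <- function(cfg, truth) {
  votu_ids <- truth$votu_id
  n <- nrow(truth)
  feats <- with_seed(child_seed(cfg$seed, "contigs"), {
    total_genes <- pmax(3L, as.integer(round(truth$genome_length / 800)))
    viral_genes <- pmax(1L, as.integer(round(total_genes * runif(n, 0.5, 0.9))))
    host_genes <- pmin(total_genes - viral_genes,
                       as.integer(round(total_genes * runif(n, 0, 0.15))))
    tibble::tibble(
      contig_id = votu_ids,
      length = truth$genome_length,
      viral_gene_count = viral_genes,
      host_gene_count = host_genes,
      total_gene_count = total_genes,
      dvf_score = runif(n, 0.91, 1.0),
      dvf_pvalue = runif(n, 0, 0.009),
      vibrant_viral = runif(n) < 0.6,
      busco_count = 0L,
      completeness = runif(n, 55, 100),
      contamination = runif(n, 0, 8)
    )
  })

  # Decoy contigs exercising every non-viral verdict.
  decoys <- tibble::tibble(
    contig_id = sprintf("decoy%02d", 1:8),
    length = c(1500, 1900, 6000, 5000, 4000, 4500, 3000, 3500),
    viral_gene_count = c(1L, 1L, 1L, 2L, 0L, 1L, 6L, 7L),
    host_gene_count = c(0L, 0L, 12L, 14L, 3L, 2L, 1L, 1L),
    total_gene_count = c(2L, 2L, 14L, 17L, 5L, 4L, 10L, 9L),
    dvf_score = c(0.5, 0.5, 0.95, 0.95, 0.5, 0.85, 0.95, 0.93),
    dvf_pvalue = c(0.5, 0.5, 0.001, 0.001, 0.5, 0.2, 0.001, 0.002),
    vibrant_viral = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    busco_count = c(0L, 0L, 0L, 0L, 0L, 0L, 2L, 0L),
    completeness = c(90, 90, 90, 90, 90, 90, 90, 30),
    contamination = rep(0, 8)
  )
  decoy_truth <- tibble::tibble(
    contig_id = decoys$contig_id,
    expected_verdict = c("too_short", "too_short", "excluded_hostlike",
                         "excluded_hostlike", "nonviral", "nonviral",
                         "rejected_busco", "rejected_completeness")
  )

  # Near-duplicate contigs that must collapse into their parent vOTU.
  n_dup <- min(5L, n)
  dup <- with_seed(child_seed(cfg$seed, "dups"), {
    parents <- sample(votu_ids, n_dup)
    plen <- truth$genome_length[match(parents, votu_ids)]
    dlen <- pmax(2001L, as.integer(round(plen * runif(n_dup, 0.6, 0.9))))
    tibble::tibble(
      contig_id = sprintf("dup%02d", seq_len(n_dup)),
      parent_id = parents,
      length = dlen,
      identity = runif(n_dup, 96, 99.5),
      coverage = runif(n_dup, 0.8, 0.95)
    )
  })
  dup_feats <- feats[match(dup$parent_id, feats$contig_id), ] |>
    dplyr::mutate(contig_id = dup$contig_id, length = dup$length)
  alignments <- tibble::tibble(
    query_id = dup$contig_id, subject_id = dup$parent_id,
    identity = dup$identity, coverage = dup$coverage
  )

  # Protein hits supporting the planted family by the voting quorum.
  hit_rows <- with_seed(child_seed(cfg$seed, "hits"), {
    purrr::map(seq_len(n), function(i) {
      fam <- truth$family[i]
      genes <- feats$total_gene_count[i]
      if (fam == "unclassified") {
        # sub-threshold hits only: removed by the 30% identity filter
        n_hit <- min(genes, 2L)
        return(tibble::tibble(
          votu_id = truth$votu_id[i],
          protein_id = sprintf("%s_p%03d", truth$votu_id[i], seq_len(n_hit)),
          target_family = "Siphoviridae",
          percent_identity = runif(n_hit, 15, 25),
          query_coverage = runif(n_hit, 55, 100),
          subject_coverage = runif(n_hit, 55, 100),
          bit_score = runif(n_hit, 60, 200)
        ))
      } else {
        quorum <- if (genes < 30) floor(genes / 5) + 1L else 10L
        n_hit <- min(genes, quorum + rbinom(1, 3, 0.5))
        target <- fam
      }
      if (n_hit == 0) return(NULL)
      tibble::tibble(
        votu_id = truth$votu_id[i],
        protein_id = sprintf("%s_p%03d", truth$votu_id[i], seq_len(n_hit)),
        target_family = target,
        percent_identity = runif(n_hit, 35, 95),
        query_coverage = runif(n_hit, 55, 100),
        subject_coverage = runif(n_hit, 55, 100),
        bit_score = runif(n_hit, 60, 400)
      )
    })
  })
  protein_hits <- dplyr::bind_rows(hit_rows)

  host_rows <- with_seed(child_seed(cfg$seed, "hosts"), {
    purrr::map(seq_len(n), function(i) {
      if (is.na(truth$host[i])) return(NULL)
      u <- runif(1)
      if (u < 0.6) {
        tibble::tibble(votu_id = truth$votu_id[i],
                       host_genome_id = truth$host[i],
                       kind = "crispr_spacer",
                       bit_score = runif(1, 45, 90),
                       percent_identity = NA_real_,
                       viral_coverage = NA_real_)
      } else if (u < 0.8) {
        tibble::tibble(votu_id = truth$votu_id[i],
                       host_genome_id = truth$host[i],
                       kind = "genome_alignment",
                       bit_score = NA_real_,
                       percent_identity = runif(1, 90, 99.9),
                       viral_coverage = runif(1, 0.3, 0.9))
      } else {
        NULL  # ~20% of vOTUs get no host evidence
      }
    })
  })
  host_evidence <- dplyr::bind_rows(host_rows)
  if (nrow(host_evidence) == 0) {
    host_evidence <- tibble::tibble(votu_id = character(),
                                    host_genome_id = character(),
                                    kind = character(), bit_score = numeric(),
                                    percent_identity = numeric(),
                                    viral_coverage = numeric())
  }

  genomes <- with_seed(child_seed(cfg$seed, "genomes"), {
    setNames(
      vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), truth$genome_length[i],
                     replace = TRUE), collapse = "")
      }, character(1)),
      votu_ids
    )
  })

  list(contig_features = dplyr::bind_rows(feats, dup_feats, decoys),
       contig_truth = dplyr::bind_rows(
         tibble::tibble(contig_id = c(votu_ids, dup$contig_id),
                        expected_verdict = "viral"),
         decoy_truth),
       alignments = alignments,
       duplicates = dup,
       protein_hits = protein_hits,
       spacer_hits = dplyr::filter(host_evidence, .data$kind == "crispr_spacer"),
       genome_aln_hits = dplyr::filter(host_evidence,
                                       .data$kind == "genome_alignment"),
       host_evidence = host_evidence,
       genomes = genomes)
}

#' @export
print.virosig_study <- function(x, ...) {
  cat("Synthetic virome study:", x$cohort_id, "\n")
  cat(sprintf("  %d vOTUs (%d case-enriched, %d control-enriched planted)\n",
              nrow(x$truth), sum(x$truth$planted == "case_enriched"),
              sum(x$truth$planted == "control_enriched")))
  cat(sprintf("  %d samples (%d subjects x VLP/bulk), effect fold %.1f\n",
              nrow(x$samples), nrow(x$samples) / 2, x$config$effect_fold))
  invisible(x)
}
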
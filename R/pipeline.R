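#' Run the full virome association pipeline on a synthetic study
#'
#' End-to-end driver: simulate (or accept) a study, triage contigs, cluster
#' viral contigs into vOTUs, build VLP and bulk relative-abundance profiles,
#' annotate vOTUs, compute diversity statistics, call dual-modality
#' case-control signatures, and validate them with random-forest
#' classifiers. With `out_dir` set, every stage's table is written to disk
#' together with a checksum manifest; identical config and seed yield
#' byte-identical outputs.
#'
#' @param config A [sim_config()]; ignored when `study` is supplied.
#' @param study Optionally a pre-generated `virosig_study`.
#' @param out_dir Optional output directory.
#' @param alpha Signature q-value threshold (default 0.05).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param top_k Features taken per dataset for the reduced classifier
#'   (default 5).
#' @param ntree Random-forest trees (default 500).
#' @return An object of class `virosig_run`: list with `study`, `triage`,
#'   `catalog`, `profiles` (per modality), `annotation`, `alpha`,
#'   `permanova` (modality and per-modality group effects), `signatures`,
#'   `cv` (per modality), `selected_features`, `transfer_auc` and, when
#'   written, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), study = NULL, out_dir = NULL,
                         alpha = 0.05, n_perm = 999, top_k = 5, ntree = 500) {
  if (is.null(study)) study <- simulate_cohort(config)
  cfg <- study$config

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  triage <- run_stage("triage", triage_contigs(study$contig_features))
  viral_ids <- triage$contig_id[triage$verdict == "viral"]

  catalog <- run_stage("cluster", {
    lengths <- setNames(study$contig_features$length,
                        study$contig_features$contig_id)[viral_ids]
    aln <- study$alignments |>
      dplyr::filter(.data$query_id %in% viral_ids,
                    .data$subject_id %in% viral_ids)
    cluster_votus(lengths, aln)
  })
  votu_ids <- sort(unique(catalog$representative_id))

  profiles <- run_stage("profile", {
    ds <- study$depth_store |>
      dplyr::filter(.data$votu_id %in% votu_ids)
    cc <- study$confirm_counts |>
      dplyr::filter(.data$votu_id %in% votu_ids)
    prof <- profile_abundance(ds, cc)
    split_ids <- split(study$samples$sample_id, study$samples$modality)
    list(vlp = dplyr::filter(prof, .data$sample_id %in% split_ids$vlp),
         bulk = dplyr::filter(prof, .data$sample_id %in% split_ids$bulk))
  })

  annotation <- run_stage("annotate", {
    gene_counts <- setNames(study$contig_features$total_gene_count,
                            study$contig_features$contig_id)[votu_ids]
    annotate_votus(dplyr::filter(study$protein_hits,
                                 .data$votu_id %in% votu_ids),
                   gene_counts,
                   host_evidence = dplyr::filter(study$host_evidence,
                                                 .data$votu_id %in% votu_ids),
                   votu_ids = votu_ids)
  })

  diversity <- run_stage("diversity", {
    kingdoms <- setNames(annotation$kingdom, annotation$votu_id)
    alpha_tabs <- purrr::map(
      c(all = "all", eukaryotic = "eukaryotic", prokaryotic = "prokaryotic"),
      function(sub) {
        dplyr::bind_rows(purrr::imap(profiles, function(p, mod) {
          alpha_diversity(p, kingdoms, subset = sub) |>
            dplyr::mutate(modality = mod, subset = sub)
        }))
      }
    )
    alpha_tab <- dplyr::bind_rows(alpha_tabs) |>
      dplyr::left_join(study$samples[, c("sample_id", "group")],
                       by = "sample_id")

    all_prof <- dplyr::bind_rows(profiles)
    d_all <- bray_curtis(all_prof)
    modality <- setNames(study$samples$modality, study$samples$sample_id)
    group <- setNames(study$samples$group, study$samples$sample_id)
    perm <- list(
      modality = permanova(d_all, modality, n_perm = n_perm,
                           seed = child_seed(cfg$seed, "perm:modality")),
      group_vlp = permanova(bray_curtis(profiles$vlp), group,
                            n_perm = n_perm,
                            seed = child_seed(cfg$seed, "perm:vlp")),
      group_bulk = permanova(bray_curtis(profiles$bulk), group,
                             n_perm = n_perm,
                             seed = child_seed(cfg$seed, "perm:bulk"))
    )
    list(alpha = alpha_tab, permanova = perm,
         pcoa = pcoa_ordination(d_all))
  })

  signatures <- run_stage("signatures", {
    call_signatures(profiles$vlp, profiles$bulk, study$samples,
                    alpha = alpha)
  })

  ml <- run_stage("classify", {
    sig_ids <- signatures$results$votu_id[
      signatures$results$status %in% c("case_enriched", "control_enriched")]
    feat_ids <- if (length(sig_ids) >= 2) sig_ids else {
      signatures$results$votu_id[signatures$results$tested_vlp &
                                   signatures$results$tested_bulk]
    }
    bundles <- purrr::imap(profiles, function(p, mod) {
      m <- profile_matrix(p)[, feat_ids, drop = FALSE]
      list(features = m,
           labels = study$samples$group[match(rownames(m),
                                              study$samples$sample_id)])
    })
    cv <- purrr::imap(bundles, function(b, mod) {
      cv_auc(b$features, b$labels, ntree = ntree,
             seed = child_seed(cfg$seed, paste0("cv:", mod)))
    })
    selected <- top_union(cv, k = top_k)
    transfer <- cross_dataset_auc(bundles, selected, ntree = ntree,
                                  seed = child_seed(cfg$seed, "transfer"))
    list(features = feat_ids, cv = cv, selected_features = selected,
         transfer_auc = transfer)
  })

  run <- structure(list(study = study, triage = triage, catalog = catalog,
                        profiles = profiles, annotation = annotation,
                        alpha = diversity$alpha,
                        permanova = diversity$permanova,
                        pcoa = diversity$pcoa,
                        signatures = signatures,
                        cv = ml$cv, selected_features = ml$selected_features,
                        transfer_auc = ml$transfer_auc),
                   class = "virosig_run")
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  run
}

#' @export
print.virosig_run <- function(x, ...) {
  cat("virosig pipeline run\n")
  cat(sprintf("  triage: %d/%d contigs viral\n",
              sum(x$triage$verdict == "viral"), nrow(x$triage)))
  cat(sprintf("  catalog: %d vOTUs\n",
              length(unique(x$catalog$representative_id))))
  print(x$signatures)
  cat(sprintf("  CV AUC: VLP %.3f, bulk %.3f; %d selected features\n",
              x$cv$vlp$mean_auc, x$cv$bulk$mean_auc,
              length(x$selected_features)))
  invisible(x)
}

permanova_json <- function(perm) {
  purrr::map(perm, function(p) {
    list(pseudo_F = p$pseudo_F, R2 = p$R2, p_value = p$p_value,
         n_perm = p$n_perm)
  })
}

#' Write a pipeline run's outputs and checksum manifest
#'
#' @param run A `virosig_run`.
#' @param out_dir Output directory.
#' @return The manifest tibble (`file`, `md5`), invisibly also written as
#'   `manifest.tsv`.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) write_tsv_file(x, file.path(out_dir, f))
  w(run$triage, "triage.tsv")
  w(run$catalog, "clusters.tsv")
  w(run$profiles$vlp, "profile_vlp.tsv")
  w(run$profiles$bulk, "profile_bulk.tsv")
  w(run$annotation, "annotation.tsv")
  w(run$alpha, "alpha.tsv")
  w(run$signatures$results, "signatures.tsv")
  w(tidy(run$pcoa), "pcoa.tsv")
  jsonlite::write_json(permanova_json(run$permanova),
                       file.path(out_dir, "permanova.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(run$signatures$concordance),
                       file.path(out_dir, "concordance.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    purrr::map(run$cv, function(cv) {
      list(mean_auc = cv$mean_auc, fold_aucs = cv$fold_aucs$auc,
           top_features = head(cv$feature_ranking$feature, 10))
    }),
    file.path(out_dir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(run$selected_features,
             file.path(out_dir, "selected_features.txt"))
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.tsv")
  manifest <- tibble::tibble(
    file = sort(files),
    md5 = unname(tools::md5sum(file.path(out_dir, sort(files))))
  )
  write_tsv_file(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}
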
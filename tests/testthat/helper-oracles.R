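# Independent oracles used to cross-check the package implementations.
# Each is written from the rule/formula definition, not from the package code.

# Truth-table reimplementation of the triage decision rules for one contig.
oracle_triage_row <- function(r) {
  if (!(r$length > 2000)) return("too_short")
  if (r$host_gene_count > 10 && r$host_gene_count > 5 * r$viral_gene_count) {
    return("excluded_hostlike")
  }
  candidate <- (r$viral_gene_count > r$host_gene_count) ||
    (r$dvf_score > 0.90 && r$dvf_pvalue < 0.01) ||
    isTRUE(r$vibrant_viral)
  if (!candidate) return("nonviral")
  if (r$total_gene_count >= 1 &&
      r$busco_count / r$total_gene_count >= 0.05) {
    return("rejected_busco")
  }
  if (!(r$completeness > 50)) return("rejected_completeness")
  "viral"
}

# Explicit sort / slice / mean trimmed-depth oracle.
oracle_trimmed <- function(x) {
  l <- length(x)
  k <- floor(0.1 * l)
  s <- sort(x)
  if (k > 0) s <- s[-c(seq_len(k), (l - k + 1):l)]
  mean(s)
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of the
# C(n1+n2, n1) rank assignments (no ties assumed).
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  w_obs <- sum(rank(c(x, y))[seq_len(n1)])
  sets <- combn(n, n1)
  w_all <- colSums(matrix(seq_len(n)[sets], nrow = n1))
  pl <- mean(w_all <= w_obs)
  pu <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pu))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(tbl) {
  m <- matrix(as.numeric(tbl), 2, 2)
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Literal step-up Benjamini-Hochberg formula:
# q(i) = min over j with p(j) >= p(i) of p(j) * m / rank(j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    j <- which(p >= p[i])
    min(1, min(p[j] * m / r[j]))
  }, numeric(1))
}

# AUC by explicit case/control pair enumeration, ties as 1/2.
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Independent greedy longest-first centroid clustering over a similarity
# lookup function sim(a, b) -> c(identity, coverage).
oracle_greedy <- function(lengths, sim, id_thr = 95, cov_thr = 0.70) {
  ord <- names(lengths)[order(-unname(lengths), names(lengths))]
  reps <- character(0)
  out <- setNames(character(length(ord)), ord)
  for (s in ord) {
    assigned <- NA_character_
    for (cen in reps) {
      sv <- sim(s, cen)
      if (sv[1] >= id_thr && sv[2] >= cov_thr) {
        assigned <- cen
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, s)
      assigned <- s
    }
    out[s] <- assigned
  }
  out
}

# Small fast study configuration for structural tests.
tiny_config <- function(seed = 1, ...) {
  sim_config(n_case = 5, n_control = 5, n_votus = 10,
             n_planted_case_enriched = 2, n_planted_control_enriched = 2,
             genome_length_range = c(2000, 3000), seed = seed, ...)
}

# Random contig feature rows spanning all rule boundaries.
random_features <- function(n, seed = 1) {
  withr::with_seed(seed, {
    total <- sample(0:40, n, replace = TRUE)
    viral <- vapply(total, function(t) sample(0:max(t, 0), 1), integer(1))
    host <- vapply(total - viral, function(t) sample(0:max(t, 0), 1),
                   integer(1))
    busco <- vapply(total, function(t) sample(0:max(t, 0), 1), integer(1))
    tibble::tibble(
      contig_id = sprintf("c%04d", seq_len(n)),
      length = sample(c(1500, 1999, 2000, 2001, 3000, 150000), n,
                      replace = TRUE),
      viral_gene_count = viral,
      host_gene_count = host,
      total_gene_count = total,
      dvf_score = round(runif(n), 2),
      dvf_pvalue = round(runif(n, 0, 0.02), 3),
      vibrant_viral = runif(n) < 0.3,
      busco_count = busco,
      completeness = sample(c(10, 49.9, 50, 50.1, 90, 100), n, replace = TRUE),
      contamination = runif(n, 0, 20)
    )
  })
}
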
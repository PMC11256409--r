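#' Alpha diversity on a kingdom subset
#'
#' Observed richness and Shannon index (natural log) of each sample,
#' restricted to the vOTUs of one kingdom (eukaryotic or prokaryotic
#' viruses) or computed over all vOTUs. Abundances are renormalised within
#' the subset before the Shannon computation, matching the proportion
#' handling of standard diversity routines.
#'
#' @param profile Long tibble `sample_id`, `votu_id`, `abundance` or a
#'   sample-by-vOTU matrix.
#' @param kingdom_map Named character vector vOTU -> kingdom; required unless
#'   `subset = "all"`.
#' @param subset One of `"all"`, `"eukaryotic"`, `"prokaryotic"`.
#' @return A tibble `sample_id`, `observed`, `shannon` (nats). Samples with
#'   no abundance in the subset get `(0, 0)`.
#' @examples
#' m <- matrix(c(0.5, 0.5, 1, 0), 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("vA", "vB")))
#' alpha_diversity(m)
#' @export
alpha_diversity <- function(profile, kingdom_map = NULL, subset = "all") {
  assert_that(subset %in% c("all", "eukaryotic", "prokaryotic"),
              "subset must be 'all', 'eukaryotic' or 'prokaryotic'")
  m <- if (is.matrix(profile)) profile else profile_matrix(profile)
  if (subset != "all") {
    assert_that(!is.null(kingdom_map),
                "kingdom_map is required for a kingdom subset")
    keep <- colnames(m)[kingdom_map[colnames(m)] %in% subset]
    m <- m[, keep, drop = FALSE]
  }
  observed <- rowSums(m > 0)
  shannon <- vegan::diversity(m, index = "shannon")
  shannon[observed == 0] <- 0
  tibble::tibble(sample_id = rownames(m),
                 observed = as.integer(observed),
                 shannon = as.numeric(shannon))
}

#' Square-root Bray-Curtis distance matrix
#'
#' Element-wise square-root transformation of the relative abundance matrix
#' followed by Bray-Curtis dissimilarity between samples.
#'
#' @param profile Long tibble or sample-by-vOTU matrix of nonnegative
#'   abundances.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return A symmetric `dist`-compatible matrix with zero diagonal, entries
#'   in \[0, 1\]. Pairs of all-zero samples get distance 0 with a warning.
#' @export
bray_curtis <- function(profile, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  m <- if (is.matrix(profile)) profile else profile_matrix(profile)
  assert_that(all(m >= 0), "abundances must be nonnegative")
  if (transform == "sqrt") m <- sqrt(m)
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (any(is.nan(d))) {
    warn("all-zero sample pair(s); their Bray-Curtis distance is set to 0")
    d[is.nan(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: Gower-centered
#' double-centred matrix, eigendecomposition, coordinates scaled by the
#' square roots of the positive eigenvalues, axis variance relative to the
#' sum of positive eigenvalues.
#'
#' @param d Symmetric distance matrix (matrix or `dist`).
#' @return An object of class `virosig_pcoa`: list with `coordinates`
#'   (samples x axes matrix, columns `PCo1`, `PCo2`, ...),
#'   `explained_variance` (fractions) and `eigenvalues`.
#' @export
pcoa_ordination <- function(d) {
  m <- as.matrix(d)
  assert_that(nrow(m) >= 3, "PCoA requires at least 3 samples")
  assert_that(max(abs(m - t(m))) < 1e-12, "distance matrix must be symmetric")
  res <- ape::pcoa(stats::as.dist(m))
  pos <- res$values$Eigenvalues > sqrt(.Machine$double.eps)
  ev <- res$values$Eigenvalues[pos]
  coords <- res$vectors[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  rownames(coords) <- rownames(m)
  structure(list(coordinates = coords,
                 explained_variance = ev / sum(ev),
                 eigenvalues = ev),
            class = "virosig_pcoa")
}

#' @export
print.virosig_pcoa <- function(x, ...) {
  cat("PCoA ordination:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "positive axes\n")
  cat("Variance explained (first axes):",
      paste0(round(100 * head(x$explained_variance, 3), 1), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.virosig_pcoa <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "sample_id")
}

#' @export
glance.virosig_pcoa <- function(x, ...) {
  tibble::tibble(n_axes = ncol(x$coordinates),
                 var_axis1 = x$explained_variance[1],
                 var_axis2 = x$explained_variance[2] %||% NA_real_)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance with the standard one-way
#' decomposition: `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `R2 = 1 - SS_within / SS_total`, and
#' `F = (SS_between / (k - 1)) / (SS_within / (N - k))`. The p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` over seeded label permutations.
#' The permutation stream is generated after sorting samples by id, so the
#' result is invariant to input row order.
#'
#' @param d Symmetric distance matrix with dimnames = sample ids.
#' @param groups Named character vector (or factor) of group labels per
#'   sample id.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `virosig_permanova`: list with `pseudo_F`,
#'   `R2`, `p_value`, `n_perm`, `df` and the group sizes.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  m <- as.matrix(d)
  ids <- rownames(m)
  assert_that(!is.null(ids), "distance matrix must have sample id dimnames")
  assert_that(all(ids %in% names(groups)),
              "every sample needs a group label")
  ord <- order(ids)
  m <- m[ord, ord]
  g <- as.character(groups[rownames(m)])
  tab <- table(g)
  assert_that(length(tab) >= 2, "PERMANOVA needs at least 2 groups")
  assert_that(all(tab >= 2), "every group needs at least 2 samples")

  d2 <- m^2
  n <- nrow(m)
  k <- length(tab)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_stat <- function(labels) {
    ss_within <- 0
    for (lev in unique(labels)) {
      idx <- which(labels == lev)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ss_between <- ss_total - ss_within
    c(F = (ss_between / (k - 1)) / (ss_within / (n - k)),
      R2 = 1 - ss_within / ss_total)
  }
  obs <- f_stat(g)
  perm_f <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) f_stat(sample(g))[["F"]], numeric(1))
  })
  structure(list(pseudo_F = unname(obs[["F"]]),
                 R2 = unname(obs[["R2"]]),
                 p_value = (1 + sum(perm_f >= obs[["F"]])) / (1 + n_perm),
                 n_perm = n_perm,
                 df = c(between = k - 1, within = n - k),
                 group_sizes = tab),
            class = "virosig_permanova")
}

#' @export
print.virosig_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_perm))
  invisible(x)
}

#' @export
tidy.virosig_permanova <- function(x, ...) {
  tibble::tibble(term = "group", df = x$df[["between"]],
                 pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value)
}

#' @export
glance.virosig_permanova <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value,
                 n_perm = x$n_perm)
}

#' Spearman rank correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A tibble `rho`, `p_value`. Constant input yields `NA` with a
#'   warning.
#' @export
spearman_cor <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector; Spearman rho is undefined")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}
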
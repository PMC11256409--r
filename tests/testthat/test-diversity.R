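mk_matrix <- function(rows, samples = NULL, votus = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- votus %||% paste0("v", seq_len(ncol(m)))
  m
}

test_that("observed and Shannon indices match closed forms", {
  m <- mk_matrix(list(c(0.5, 0.5, 0, 0), c(1, 0, 0, 0),
                      c(0.25, 0.25, 0.25, 0.25)))
  out <- alpha_diversity(m)
  expect_equal(out$observed, c(2L, 1L, 4L))
  expect_equal(out$shannon, c(log(2), 0, log(4)))
})

test_that("kingdom subsets renormalise before Shannon", {
  m <- mk_matrix(list(c(0.05, 0.05, 0.9)))
  km <- c(v1 = "eukaryotic", v2 = "eukaryotic", v3 = "prokaryotic")
  out <- alpha_diversity(m, km, subset = "eukaryotic")
  expect_equal(out$observed, 2L)
  expect_equal(out$shannon, log(2))  # 0.05/0.05 renormalised to 0.5/0.5
  # empty subset -> (0, 0)
  m2 <- mk_matrix(list(c(0, 0, 0.9)))
  out2 <- alpha_diversity(m2, km, subset = "eukaryotic")
  expect_equal(c(out2$observed, out2$shannon), c(0, 0))
})

test_that("Shannon is maximal at the uniform distribution", {
  withr::with_seed(4, {
    for (k in c(3, 7, 15)) {
      p <- relative_abundance(rgamma(k, 1) + 0.01)
      s <- alpha_diversity(mk_matrix(list(p), votus = paste0("v", 1:k)))
      expect_lte(s$shannon, log(k) + 1e-12)
    }
  })
})

test_that("square-root Bray-Curtis matches hand arithmetic and bounds", {
  m <- mk_matrix(list(c(4, 1), c(1, 1)))
  d <- bray_curtis(m)
  expect_equal(d["s1", "s2"], 0.2)  # sqrt -> (2,1),(1,1); (1+0)/(3+2)
  expect_equal(d["s1", "s1"], 0)
  # identical rows -> 0, disjoint support -> 1
  m2 <- mk_matrix(list(c(0.3, 0.7), c(0.3, 0.7), c(0, 0)))
  m2[3, ] <- c(0, 0)
  expect_equal(bray_curtis(m2[1:2, ])["s1", "s2"], 0)
  m3 <- mk_matrix(list(c(1, 0), c(0, 1)))
  expect_equal(bray_curtis(m3)["s1", "s2"], 1)
  # symmetry and [0,1] on random compositional rows
  withr::with_seed(9, {
    mr <- t(replicate(6, relative_abundance(rgamma(8, 1))))
  })
  rownames(mr) <- paste0("r", 1:6); colnames(mr) <- paste0("v", 1:8)
  dr <- bray_curtis(mr)
  expect_equal(dr, t(dr))
  expect_true(all(dr >= 0 & dr <= 1))
})

test_that("all-zero sample pairs get distance 0 with a warning", {
  m <- mk_matrix(list(c(0, 0), c(0, 0), c(0.5, 0.5)))
  expect_warning(d <- bray_curtis(m), "all-zero")
  expect_equal(d["s1", "s2"], 0)
})

test_that("PCoA reproduces closed-form and round-trip geometry", {
  # 3-point equilateral metric: two positive axes at 50% each
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord <- pcoa_ordination(d)
  expect_equal(length(ord$eigenvalues), 2)
  expect_equal(ord$explained_variance, c(0.5, 0.5))
  # identical samples coincide on all axes
  m <- mk_matrix(list(c(0.5, 0.5, 0), c(0.5, 0.5, 0), c(0, 0.2, 0.8),
                      c(0.1, 0.3, 0.6)))
  ord2 <- pcoa_ordination(bray_curtis(m))
  expect_equal(ord2$coordinates["s1", ], ord2$coordinates["s2", ],
               tolerance = 1e-8)
  # Euclidean-embeddable distances are reproduced from full-rank coordinates
  withr::with_seed(2, {
    pts <- matrix(rnorm(5 * 3), 5, 3)
  })
  de <- as.matrix(dist(pts))
  dimnames(de) <- list(paste0("p", 1:5), paste0("p", 1:5))
  ord3 <- pcoa_ordination(de)
  back <- as.matrix(dist(ord3$coordinates))
  expect_equal(unname(back), unname(de), tolerance = 1e-8)
  expect_error(pcoa_ordination(de[1:2, 1:2]), "at least 3")
})

test_that("PERMANOVA agrees with vegan's one-way decomposition", {
  withr::with_seed(31, {
    m <- rbind(t(replicate(6, relative_abundance(rgamma(10, 1) + c(rep(3, 5), rep(0, 5))))),
               t(replicate(6, relative_abundance(rgamma(10, 1) + c(rep(0, 5), rep(3, 5))))))
  })
  rownames(m) <- paste0("s", 1:12); colnames(m) <- paste0("v", 1:10)
  grp <- setNames(rep(c("a", "b"), each = 6), rownames(m))
  d <- bray_curtis(m)
  fit <- permanova(d, grp, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(stats::as.dist(d) ~ g,
                       data = data.frame(g = grp), permutations = 19)
  expect_equal(fit$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(fit$R2, ad$R2[1], tolerance = 1e-10)
  expect_true(fit$R2 >= 0 && fit$R2 <= 1)
})

test_that("separated clusters reach the minimal attainable permutation p", {
  m <- mk_matrix(c(
    purrr::map(1:10, \(i) c(1, 0, 0, 0) + i * 1e-4),
    purrr::map(1:10, \(i) c(0, 0, 0, 1) + i * 1e-4)
  ))
  grp <- setNames(rep(c("a", "b"), each = 10), rownames(m))
  fit <- permanova(bray_curtis(m), grp, n_perm = 999, seed = 42)
  expect_equal(fit$p_value, 1 / 1000)
})

test_that("PERMANOVA is invariant to sample reordering under one seed", {
  withr::with_seed(6, {
    m <- t(replicate(10, relative_abundance(rgamma(6, 1))))
  })
  rownames(m) <- paste0("s", 1:10); colnames(m) <- paste0("v", 1:6)
  grp <- setNames(rep(c("a", "b"), 5), rownames(m))
  d <- bray_curtis(m)
  perm <- sample(1:10)
  d2 <- d[perm, perm]
  f1 <- permanova(d, grp, n_perm = 199, seed = 7)
  f2 <- permanova(d2, grp[perm], n_perm = 199, seed = 7)
  expect_equal(f1$p_value, f2$p_value)
  expect_equal(f1$pseudo_F, f2$pseudo_F)
})

test_that("PERMANOVA rejects degenerate designs", {
  d <- matrix(0.5, 4, 4) - 0.5 * diag(4)
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_error(permanova(d, setNames(c("a", "a", "a", "b"),
                                     rownames(d))), "at least 2 samples")
  expect_error(permanova(d, setNames(rep("a", 4), rownames(d))),
               "at least 2 groups")
})

test_that("Spearman correlation matches rank arithmetic", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_cor(1:5, -(1:5))$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  expect_warning(out <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
})

test_that("tidiers expose PCoA and PERMANOVA results as tibbles", {
  d <- matrix(1, 4, 4) - diag(4)
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  ord <- pcoa_ordination(d)
  td <- tidy(ord)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$sample_id, paste0("s", 1:4))
  fit <- permanova(d, setNames(rep(c("a", "b"), 2), rownames(d)),
                   n_perm = 49, seed = 1)
  expect_named(glance(fit), c("pseudo_F", "R2", "p_value", "n_perm"))
})
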
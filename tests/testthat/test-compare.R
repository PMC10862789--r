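test_that("the |z| union filter matches an enumeration oracle", {
  z <- rbind(a = c(0.6, 0.4, -0.7, 0, 0.5, -0.5),
             b = c(0, 0, 0, 0.9, 0, 0))
  colnames(z) <- paste0("G", 1:6)
  m <- perturbation_matrix(z)
  # strict inequality excludes +-0.5 exactly
  expect_equal(filter_by_z(m, "a", "b", 0.5), c("G1", "G3", "G4"))
  # brute-force enumeration oracle on random toys
  set.seed(21)
  for (i in 1:10) {
    zz <- matrix(round(rnorm(2 * 12), 2), 2, 12,
                 dimnames = list(c("a", "b"), paste0("G", 1:12)))
    mm <- perturbation_matrix(zz)
    thr <- runif(1, 0, 1.5)
    oracle <- colnames(zz)[vapply(seq_len(12), function(j)
      abs(zz["a", j]) > thr || abs(zz["b", j]) > thr, logical(1))]
    expect_equal(filter_by_z(mm, "a", "b", thr), oracle)
  }
  # zero matrix -> empty; threshold 0 -> any nonzero z
  z0 <- matrix(0, 2, 4, dimnames = list(c("a", "b"), paste0("G", 1:4)))
  expect_equal(filter_by_z(perturbation_matrix(z0), "a", "b", 0.5),
               character(0))
  z0[1, 2] <- 0.1
  expect_equal(filter_by_z(perturbation_matrix(z0), "a", "b", 0), "G2")
})

test_that("the filter is antitone in the threshold", {
  m <- toy_study_matrix(n_pert = 2, seed = 17)
  thresholds <- seq(0, 2, by = 0.25)
  sets <- lapply(thresholds, function(t) filter_by_z(m, "P1", "P2", t))
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("pair regression matches the closed-form OLS solution", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  z <- rbind(a = x, b = y); colnames(z) <- paste0("G", 1:5)
  m <- perturbation_matrix(z)
  r <- regress_perturbations(m, "a", "b", genes = paste0("G", 1:5))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)
  expect_equal(r$r2, 1)
  # random vectors against the normal-equations oracle, to 1e-10
  set.seed(31)
  for (i in 1:5) {
    zz <- matrix(rnorm(2 * 40), 2, 40,
                 dimnames = list(c("a", "b"), paste0("G", 1:40)))
    mm <- perturbation_matrix(zz)
    rr <- regress_perturbations(mm, "a", "b", genes = paste0("G", 1:40))
    ora <- oracle_ols(zz["a", ], zz["b", ])
    expect_equal(rr$slope, ora$slope, tolerance = 1e-10)
    expect_equal(rr$intercept, ora$intercept, tolerance = 1e-10)
    expect_equal(rr$r2, ora$r2, tolerance = 1e-10)
    # R2 equals squared Pearson r for simple regression
    expect_equal(rr$r2, cor(zz["a", ], zz["b", ])^2, tolerance = 1e-12)
  }
})

test_that("self-comparison is the identity fit; zero x-variance is flagged", {
  m <- toy_study_matrix(n_pert = 3, seed = 23)
  r <- regress_perturbations(m, "P1", "P1", threshold = 0.2)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r2, 1)
  zc <- rbind(a = rep(1, 5), b = rnorm(5)); colnames(zc) <- paste0("G", 1:5)
  expect_warning(rc <- regress_perturbations(perturbation_matrix(zc),
                                             "a", "b",
                                             genes = paste0("G", 1:5)),
                 "zero variance")
  expect_false(rc$defined)
  expect_true(is.na(rc$r2))
})

test_that("independent null perturbation pairs give near-zero R2", {
  r2s <- vapply(1:40, function(seed) {
    set.seed(seed + 1000)
    z <- matrix(rnorm(2 * 2000), 2, 2000,
                dimnames = list(c("a", "b"), sprintf("G%04d", 1:2000)))
    regress_perturbations(perturbation_matrix(z), "a", "b",
                          threshold = 0.5)$r2
  }, numeric(1))
  expect_gte(mean(r2s < 0.05), 0.95)
})

test_that("group profiles average gene-wise and strengthen shared signal", {
  m <- toy_study_matrix(n_pert = 4, seed = 29)
  # single member: identical to that perturbation's vector
  g1 <- group_profile(m, "P1")
  expect_equal(unclass(g1), m$z["P1", ], ignore_attr = TRUE)
  # mirrored profiles cancel
  z <- rbind(a = c(1, -2, 3), b = -c(1, -2, 3)); colnames(z) <- paste0("G", 1:3)
  g <- group_profile(perturbation_matrix(z), c("a", "b"))
  expect_true(all(g == 0))
  expect_error(group_profile(m, character(0)), "empty")
  # perturbations sharing a planted ISR program: their pooled profile
  # regresses onto a mito-like perturbation better than a null does
  r2 <- vapply(41:43, function(seed) {
    st <- suppressMessages(simulate_study(
      synthetic_spec(n_per_class = 10, n_genes = 300, seed = seed),
      scale = "z"))
    eif2b <- grep("EIF2B", perturbations(st$matrix), value = TRUE)
    grp <- group_profile(st$matrix, eif2b, label = "EIF2B_pool")
    c(grp = regress_perturbations(st$matrix, grp, "MITO_LIKE_001")$r2,
      null = regress_perturbations(st$matrix, "NULL_001", "MITO_LIKE_001")$r2)
  }, numeric(2))
  expect_gt(mean(r2["grp", ]), mean(r2["null", ]))
})

test_that("gene-class contrast recovers forced and planted mtDNA shifts", {
  z <- rbind(a = c(-1, -1, 0, 0, 0), b = rep(0, 5))
  colnames(z) <- c("MT-1", "MT-2", "G1", "G2", "G3")
  m <- perturbation_matrix(z)
  cc <- compare_gene_class(m, "a", "b")
  expect_equal(cc$n_class, 2)
  expect_equal(cc$per_perturbation$difference[1], -1)
  expect_equal(cc$per_perturbation$difference[2], 0)
  expect_equal(cc$between, -1)
  # unannotated flag errors, naming available flags
  expect_error(compare_gene_class(m, "a", "b", "nope"), "mtdna_encoded")
  # no flagged genes -> error
  z2 <- z; colnames(z2) <- paste0("G", 1:5)
  expect_error(compare_gene_class(perturbation_matrix(z2), "a", "b"),
               "flags no genes")
  # planted -0.8 mtDNA down-shift recovered within 4 SE
  st <- suppressMessages(simulate_study(
    synthetic_spec(n_per_class = 40, n_genes = 300, seed = 51), scale = "z"))
  mito <- grep("MITO", perturbations(st$matrix), value = TRUE)
  eif2b <- grep("EIF2B", perturbations(st$matrix), value = TRUE)
  diffs <- vapply(mito, function(p)
    compare_gene_class(st$matrix, p, eif2b[1])$per_perturbation$difference[1],
    numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - (-0.8)), 4 * se + 1e-12)
  # and the eif2b class itself shows no mtDNA shift
  diffs0 <- vapply(eif2b, function(p)
    compare_gene_class(st$matrix, p, mito[1])$per_perturbation$difference[1],
    numeric(1))
  se0 <- sd(diffs0) / sqrt(length(diffs0))
  expect_lt(abs(mean(diffs0)), 4 * se0)
})

test_that("PCA variance fractions behave and match a closed-form 2x2 oracle", {
  # variation along exactly one gene direction -> PC1 explains 100%
  n <- 10
  z <- matrix(0, n, 3, dimnames = list(paste0("P", 1:n), c("G1", "G2", "G3")))
  z[, 1] <- seq_len(n)
  pc <- pca_perturbations(perturbation_matrix(z))
  expect_equal(pc$variance_fractions[1], 1)
  # 2-gene toy: fractions equal the covariance eigenvalue ratio
  set.seed(61)
  z2 <- matrix(rnorm(200), 100, 2, dimnames = list(sprintf("P%03d", 1:100),
                                                   c("G1", "G2")))
  z2[, 2] <- 0.8 * z2[, 1] + 0.6 * z2[, 2]
  m2 <- perturbation_matrix(z2)
  pc2 <- pca_perturbations(m2)
  ev <- eigen(cov(z2))$values
  expect_equal(pc2$variance_fractions, ev / sum(ev), tolerance = 1e-10)
  # fractions: non-negative, sorted, sum to 1
  m3 <- toy_study_matrix(n_pert = 8, seed = 67)
  pc3 <- pca_perturbations(m3)
  vf <- pc3$variance_fractions
  expect_true(all(vf >= 0))
  expect_true(all(diff(vf) <= 1e-12))
  expect_equal(sum(vf), 1, tolerance = 1e-10)
  # component scores orthogonal; reconstruction reproduces centered matrix
  G <- crossprod(pc3$component_scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  centered <- scale(m3$z, center = TRUE, scale = FALSE)
  recon <- pc3$component_scores %*% t(pc3$loadings)
  expect_lt(max(abs(recon - centered)), 1e-8)
  # constant matrix -> degenerate, flagged
  z0 <- matrix(1, 4, 3, dimnames = list(paste0("P", 1:4), paste0("G", 1:3)))
  expect_warning(pc0 <- pca_perturbations(perturbation_matrix(z0)),
                 "constant")
  expect_true(pc0$degenerate)
})

test_that("a planted activation gradient dominates component 1", {
  set.seed(71)
  n_pert <- 150; n_genes <- 200
  isr <- stress_genesets()$sets$ISR$genes
  genes <- c(isr, sprintf("G%03d", seq_len(n_genes - length(isr))))
  grad <- seq(0, 4, length.out = n_pert)
  z <- matrix(rnorm(n_pert * n_genes), n_pert, n_genes,
              dimnames = list(sprintf("P%03d", 1:n_pert), genes))
  z[, isr] <- z[, isr] + grad
  pc <- pca_perturbations(perturbation_matrix(z))
  expect_gt(abs(cor(pc$component_scores[, 1], grad)), 0.9)
})
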
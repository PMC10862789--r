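test_that("activation score is the exact mean z of the set genes", {
  z <- matrix(0, 1, 6, dimnames = list("P1", c("A1", "A2", "A3", "C1", "C2", "C3")))
  m <- perturbation_matrix(z)
  s <- geneset("S", c("A1", "A2", "A3"))
  expect_equal(activation_score(m, s, "P1"), 0)
  z[1, 1:3] <- c(1, 2, 3)
  m <- perturbation_matrix(z)
  expect_equal(activation_score(m, s, "P1"), 2.0)
  # order-independence and invariance to genes outside the set
  s_rev <- geneset("S", c("A3", "A1", "A2"))
  expect_equal(activation_score(m, s_rev, "P1"),
               activation_score(m, s, "P1"))
  z[1, 4:6] <- 99
  expect_equal(activation_score(perturbation_matrix(z), s, "P1"), 2.0)
  expect_error(activation_score(m, geneset("S", "ZZ"), "P1"), "map_to_panel")
})

test_that("adding delta to every set gene shifts the score by exactly delta", {
  set.seed(5)
  for (delta in c(-2, 0.5, 1.7)) {
    z <- matrix(rnorm(8), 1, 8,
                dimnames = list("P1", paste0("G", 1:8)))
    s <- geneset("S", c("G1", "G3", "G5"))
    base <- activation_score(perturbation_matrix(z), s, "P1")
    z[1, c("G1", "G3", "G5")] <- z[1, c("G1", "G3", "G5")] + delta
    expect_equal(activation_score(perturbation_matrix(z), s, "P1"),
                 base + delta)
  }
})

test_that("Welch and Brown-Forsythe match textbook-formula oracles to 1e-10", {
  set.seed(42)
  x <- rnorm(13, mean = 1.5, sd = 1)
  y <- rnorm(19, mean = 0, sd = 1)
  genes <- c(paste0("S", 1:13), paste0("C", 1:19))
  z <- matrix(c(x, y), 1, 32, dimnames = list("P1", genes))
  m <- perturbation_matrix(z)
  s <- geneset("S", paste0("S", 1:13))
  ctrl <- geneset("CONTROL", paste0("C", 1:19))
  got <- pathway_pvalue(m, s, ctrl, "P1")
  expect_equal(got$p_value, oracle_welch_t(x, y)$p, tolerance = 1e-10)
  expect_equal(got$statistic, oracle_welch_t(x, y)$t, tolerance = 1e-10)
  expect_equal(got$bf_p_value, oracle_brown_forsythe(list(x, y))$p,
               tolerance = 1e-10)
  # unequal variances too
  y2 <- rnorm(19, 0, 3)
  z2 <- matrix(c(x, y2), 1, 32, dimnames = list("P1", genes))
  got2 <- pathway_pvalue(perturbation_matrix(z2), s, ctrl, "P1")
  expect_equal(got2$p_value, oracle_welch_t(x, y2)$p, tolerance = 1e-10)
  expect_equal(got2$bf_p_value, oracle_brown_forsythe(list(x, y2))$p,
               tolerance = 1e-10)
})

test_that("degenerate-variance conventions hold (p = 1 equal, p = 0 unequal)", {
  genes <- c(paste0("S", 1:3), paste0("C", 1:3))
  s <- geneset("S", paste0("S", 1:3))
  ctrl <- geneset("CONTROL", paste0("C", 1:3))
  z_eq <- matrix(rep(2, 6), 1, 6, dimnames = list("P1", genes))
  got <- pathway_pvalue(perturbation_matrix(z_eq), s, ctrl, "P1")
  expect_equal(got$p_value, 1)
  expect_equal(got$bf_p_value, 1)
  z_ne <- matrix(rep(c(2, 5), each = 3), 1, 6, dimnames = list("P1", genes))
  got <- pathway_pvalue(perturbation_matrix(z_ne), s, ctrl, "P1")
  expect_equal(got$p_value, 0)
  # identical groups element-wise: statistic 0, p = 1
  z_id <- matrix(rep(c(1, 2, 3), 2), 1, 6, dimnames = list("P1", genes))
  got <- pathway_pvalue(perturbation_matrix(z_id), s, ctrl, "P1")
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
})

test_that("omnibus Welch ANOVA matches the Welch (1951) formula and F = t^2", {
  set.seed(9)
  groups <- list(S1 = rnorm(8, 1), S2 = rnorm(12, 0, 2), CONTROL = rnorm(10))
  genes <- unlist(lapply(names(groups), function(n)
    paste0(n, "_", seq_along(groups[[n]]))))
  z <- matrix(unlist(groups), 1, length(genes), dimnames = list("P1", genes))
  m <- perturbation_matrix(z)
  coll <- geneset_collection(lapply(names(groups), function(n)
    geneset(n, paste0(n, "_", seq_along(groups[[n]])))))
  got <- omnibus_test(m, coll, "P1")
  ora <- oracle_welch_anova(groups)
  expect_equal(got$statistic, ora$F, tolerance = 1e-10)
  expect_equal(got$welch_anova_p, ora$p, tolerance = 1e-10)
  expect_equal(got$brown_forsythe_p, oracle_brown_forsythe(groups)$p,
               tolerance = 1e-10)
  expect_equal(nrow(got$posthoc), 2)       # each pathway vs control
  expect_true(all(got$posthoc$p_adj >= 0 & got$posthoc$p_adj <= 1))
  # two groups: Welch ANOVA F equals the squared Welch t, identical p
  coll2 <- geneset_collection(lapply(c("S1", "CONTROL"), function(n)
    geneset(n, paste0(n, "_", seq_along(groups[[n]])))))
  got2 <- omnibus_test(m, coll2, "P1")
  tt <- oracle_welch_t(groups$S1, groups$CONTROL)
  expect_equal(got2$statistic, tt$t^2, tolerance = 1e-10)
  expect_equal(got2$welch_anova_p, tt$p, tolerance = 1e-10)
  # identically replicated groups -> p = 1
  zr <- matrix(rep(c(1, 2, 3), 3), 1, 9,
               dimnames = list("P1", paste0("R", 1:9)))
  collr <- geneset_collection(list(geneset("A", paste0("R", 1:3)),
                                   geneset("B", paste0("R", 4:6)),
                                   geneset("CONTROL", paste0("R", 7:9))))
  gotr <- omnibus_test(perturbation_matrix(zr), collr, "P1")
  expect_equal(gotr$welch_anova_p, 1)
})

test_that("activation_table assembles one row per (perturbation, pathway)", {
  st <- suppressMessages(simulate_study(
    synthetic_spec(n_per_class = 4, n_genes = 150, seed = 6), scale = "z"))
  coll <- stress_genesets(arms = FALSE)
  tab <- suppressMessages(activation_table(st$matrix, coll))
  expect_s3_class(tab, "activation_table")
  expect_equal(nrow(tab), 24 * 4)  # 24 perturbations x 4 pathways
  expect_false(any(duplicated(tab[c("perturbation", "pathway")])))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$bf_p_value >= 0 & tab$bf_p_value <= 1))
  expect_equal(tab$neg_log10_p, -log10(tab$p_value))
  # scores agree with the single-perturbation operation
  mapped <- suppressMessages(map_to_panel(coll, panel_genes(st$matrix)))
  i <- which(tab$perturbation == "MITO_LIKE_002" & tab$pathway == "ISR")
  expect_equal(tab$score[i],
               activation_score(st$matrix, mapped$sets$ISR, "MITO_LIKE_002"))
  # empty perturbation list -> empty table
  empty <- activation_table(st$matrix, coll, perts = character(0))
  expect_equal(nrow(empty), 0)
  # TSV export has the fixed column order
  f <- withr::local_tempfile(fileext = ".tsv")
  write_activation_table(tab, f)
  expect_equal(names(read.delim(f)),
               c("perturbation", "target_gene", "pathway", "score",
                 "n_genes_used", "p_value", "bf_p_value", "neg_log10_p",
                 "significant"))
})

test_that("Benjamini-Hochberg adjustment is applied within pathway", {
  st <- suppressMessages(simulate_study(
    synthetic_spec(n_per_class = 10, n_genes = 150, seed = 8), scale = "z"))
  coll <- small_calibration_collection()
  raw <- suppressMessages(activation_table(st$matrix, coll, adjust = "none"))
  bh <- suppressMessages(activation_table(st$matrix, coll, adjust = "BH"))
  expect_equal(bh$p_value, p.adjust(raw$p_value, "BH"))
  expect_true(all(bh$p_value >= raw$p_value))
  expect_true(sum(bh$significant) <= sum(raw$significant))
})

test_that("knockdown correlation: identity gives r = 1, constants are flagged", {
  set.seed(13)
  coll <- small_calibration_collection()
  n <- 30
  kd <- runif(n, 0.2, 0.95)
  genes <- c(coll$sets$ISR$genes, coll$sets$CONTROL$genes)
  # construct scores equal to knockdown: every ISR gene's z = kd
  z <- matrix(0, n, length(genes),
              dimnames = list(sprintf("P%02d", 1:n), genes))
  z[, coll$sets$ISR$genes] <- kd
  pm <- data.frame(perturbation = rownames(z), knockdown_fraction = kd)
  m <- perturbation_matrix(z, pert_meta = pm)
  tab <- suppressMessages(activation_table(m, coll))
  ck <- correlate_knockdown(tab, m)
  expect_equal(ck$r[ck$pathway == "ISR"], 1, tolerance = 1e-12)
  # constant scores -> zero variance -> undefined, flagged not thrown
  z0 <- z; z0[, coll$sets$ISR$genes] <- 0.5
  m0 <- perturbation_matrix(z0, pert_meta = pm)
  tab0 <- suppressMessages(activation_table(m0, coll))
  ck0 <- correlate_knockdown(tab0, m0)
  expect_true(is.na(ck0$r))
  expect_match(ck0$note, "zero variance")
  # < 3 usable pairs -> undefined, with the exclusion logged
  pm3 <- pm; pm3$knockdown_fraction[3:n] <- NA
  m3 <- perturbation_matrix(z, pert_meta = pm3)
  tab3 <- suppressMessages(activation_table(m3, coll))
  expect_message(ck3 <- correlate_knockdown(tab3, m3), "excluding")
  expect_true(is.na(ck3$r))
  expect_match(ck3$note, "fewer than 3")
})

test_that("scores built independent of knockdown show no correlation", {
  # simulated studies draw knockdown from a Beta independent of effects,
  # so |r| should be small for a reasonably large class
  rs <- vapply(1:5, function(seed) {
    st <- suppressMessages(simulate_study(synthetic_spec(
      classes = list(eif2b_like = perturbation_program(c(ISR = 1.5))),
      n_per_class = 200, n_genes = 100, seed = seed), scale = "z"))
    tab <- suppressMessages(activation_table(
      st$matrix, small_calibration_collection()))
    ck <- correlate_knockdown(tab, st$matrix)
    abs(ck$r[ck$pathway == "ISR"])
  }, numeric(1))
  expect_gte(mean(rs < 0.2), 0.95)
})
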
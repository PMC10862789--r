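# Internal statistical kernels ------------------------------------------------
#
# Degenerate-variance conventions (batch runs over thousands of perturbations
# must not abort): when both groups are constant, p = 1 if the constants are
# equal, else p = 0; when a variance test sees two spread-free groups the
# spreads are equal, so p = 1. All conventions surface in the returned values,
# never as exceptions.

.welch2 <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (equal) 0 else Inf,
                df = NA_real_, p.value = if (equal) 1 else 0,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, degenerate = FALSE)
}

.brown_forsythe <- function(values, group) {
  group <- factor(group)
  spread_free <- all(vapply(split(values, group),
                            function(v) stats::var(v) == 0, logical(1)))
  if (spread_free)
    return(list(statistic = 0, p.value = 1, degenerate = TRUE))
  lt <- car::leveneTest(values, group, center = stats::median)
  p <- lt[["Pr(>F)"]][1]
  if (is.na(p)) p <- 1
  list(statistic = lt[["F value"]][1], p.value = p, degenerate = FALSE)
}

.welch_anova <- function(values, group) {
  group <- factor(group)
  if (all(vapply(split(values, group),
                 function(v) stats::var(v) == 0, logical(1)))) {
    mns <- vapply(split(values, group), mean, numeric(1))
    equal <- isTRUE(all.equal(max(mns), min(mns)))
    return(list(statistic = if (equal) 0 else Inf, df1 = NA, df2 = NA,
                p.value = if (equal) 1 else 0, degenerate = TRUE))
  }
  ht <- stats::oneway.test(values ~ group, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p.value = ht$p.value,
       degenerate = FALSE)
}

# Games-Howell pairwise comparisons against a reference group. Uses the
# studentized range with Welch-Satterthwaite df; k = total number of groups.
.games_howell <- function(groups, reference) {
  k <- length(groups)
  ref <- groups[[reference]]
  nr <- length(ref); vr <- stats::var(ref); mr <- mean(ref)
  others <- setdiff(names(groups), reference)
  out <- data.frame(pathway = others, diff = NA_real_, se = NA_real_,
                    df = NA_real_, q = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(others)) {
    g <- groups[[others[i]]]
    ng <- length(g); vg <- stats::var(g)
    se2 <- vg / ng + vr / nr
    d <- mean(g) - mr
    if (se2 == 0) {
      out$diff[i] <- d
      out$p_adj[i] <- if (isTRUE(all.equal(d, 0))) 1 else 0
      next
    }
    df <- se2^2 / ((vg / ng)^2 / (ng - 1) + (vr / nr)^2 / (nr - 1))
    q <- abs(d) / sqrt(se2 / 2)
    out$diff[i] <- d
    out$se[i] <- sqrt(se2)
    out$df[i] <- df
    out$q[i] <- q
    out$p_adj[i] <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  }
  out
}

.mapped_values <- function(m, set, pert) {
  miss <- setdiff(set$genes, colnames(m$z))
  if (length(miss))
    stop("gene set '", set$name, "' is not mapped to the matrix panel (",
         length(miss), " gene(s) absent); run map_to_panel() first")
  m$z[pert, set$genes]
}

# User-facing operations -------------------------------------------------------

#' Pathway activation score
#'
#' The activation score of a pathway in one perturbation is the arithmetic
#' mean of the z-scores of the pathway's target genes in that perturbation.
#' It is deterministic, order-independent, unaffected by genes outside the
#' set, and shifts by exactly \eqn{\delta} when every set gene's z shifts by
#' \eqn{\delta}.
#'
#' @param m A [perturbation_matrix()].
#' @param set A [geneset()] already mapped to the matrix panel
#'   (see [map_to_panel()]).
#' @param pert Perturbation identifier.
#' @return The mean z-score (length-1 numeric).
#' @export
activation_score <- function(m, set, pert) {
  stopifnot(inherits(m, "perturbation_matrix"), inherits(set, "geneset"))
  if (!pert %in% rownames(m$z)) stop("unknown perturbation: ", pert)
  mean(.mapped_values(m, set, pert))
}

#' Pathway significance versus the control gene set
#'
#' For one perturbation, compares the z-scores of the pathway's target genes
#' with those of the control panel: the mean shift by Welch's
#' unequal-variance t test (`p_value`) and the spread difference by the
#' Brown-Forsythe test, i.e. the median-centred Levene test (`bf_p_value`).
#'
#' @inheritParams activation_score
#' @param control The mapped control [geneset()].
#' @return Named list: `p_value`, `bf_p_value`, `statistic` (Welch t), `df`.
#' @export
pathway_pvalue <- function(m, set, control, pert) {
  x <- .mapped_values(m, set, pert)
  y <- .mapped_values(m, control, pert)
  if (length(x) < 2L || length(y) < 2L)
    stop("both gene sets need >= 2 mapped genes")
  w <- .welch2(x, y)
  bf <- .brown_forsythe(c(x, y), rep(c("set", "control"), c(length(x), length(y))))
  list(p_value = w$p.value, bf_p_value = bf$p.value,
       statistic = w$statistic, df = w$df)
}

#' Omnibus multi-pathway test for one perturbation
#'
#' The k-group analogue of [pathway_pvalue()]: Welch's heteroscedastic
#' one-way ANOVA across all pathway gene-set z-value groups plus the control
#' group, the Brown-Forsythe variance test across the same groups, and
#' Games-Howell post hoc comparisons of each pathway against the control
#' panel. With exactly one pathway plus control, the Welch ANOVA reduces to
#' the two-group Welch t test (F = t-squared, identical p).
#'
#' @param m A [perturbation_matrix()].
#' @param coll A mapped [geneset_collection()] with a designated control set.
#' @param pert Perturbation identifier.
#' @return List with `welch_anova_p`, `brown_forsythe_p`, `statistic`
#'   (Welch F), and `posthoc` (data.frame of Games-Howell comparisons vs
#'   control).
#' @export
omnibus_test <- function(m, coll, pert) {
  stopifnot(inherits(coll, "geneset_collection"))
  if (is.null(coll$control_name)) stop("collection has no control set")
  groups <- lapply(coll$sets, function(s) .mapped_values(m, s, pert))
  if (length(groups) < 2L) stop("need >= 2 gene sets for the omnibus test")
  values <- unlist(groups, use.names = FALSE)
  grp <- rep(names(groups), lengths(groups))
  wa <- .welch_anova(values, grp)
  bf <- .brown_forsythe(values, grp)
  ph <- .games_howell(groups, coll$control_name)
  list(welch_anova_p = wa$p.value, brown_forsythe_p = bf$p.value,
       statistic = wa$statistic, df1 = wa$df1, df2 = wa$df2, posthoc = ph)
}

#' Score every perturbation against every pathway
#'
#' The package's central fitting function. For each requested perturbation
#' and each pathway set in the collection it computes the activation score
#' (mean z of the set genes), the Welch p-value against the control panel,
#' and the Brown-Forsythe variance p-value, assembling the table behind the
#' volcano representation (score vs -log10 p). Row-level failures are
#' logged and the batch continues.
#'
#' @param m A [perturbation_matrix()].
#' @param coll A [geneset_collection()]; it is mapped to the matrix panel
#'   internally via [map_to_panel()].
#' @param perts Perturbation identifiers; defaults to all.
#' @param alpha Significance level (default 0.05; 0.01 and 0.005 are the
#'   conventional reporting tiers).
#' @param adjust Multiple-testing adjustment across perturbations, applied
#'   within each pathway: `"none"` (default) or any [stats::p.adjust()]
#'   method such as `"BH"`.
#' @param min_fraction Passed to [map_to_panel()].
#' @return An object of class `"activation_table"`: a data.frame with
#'   columns `perturbation`, `target_gene`, `pathway`, `score`,
#'   `n_genes_used`, `p_value`, `bf_p_value`, `neg_log10_p`, `significant`,
#'   plus attributes `alpha`, `adjust` and `control`.
#' @seealso [plot.activation_table()], [write_activation_table()],
#'   [correlate_knockdown()]
#' @export
activation_table <- function(m, coll, perts = NULL, alpha = 0.05,
                             adjust = "none", min_fraction = 0.5) {
  stopifnot(inherits(m, "perturbation_matrix"),
            inherits(coll, "geneset_collection"))
  if (is.null(coll$control_name)) stop("collection has no control set")
  if (is.null(perts)) perts <- perturbations(m)
  bad <- setdiff(perts, perturbations(m))
  if (length(bad)) stop("unknown perturbation(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  mapped <- suppressMessages(map_to_panel(coll, panel_genes(m), min_fraction))
  ctrl <- control_set(mapped)
  paths <- pathway_sets(mapped)
  if (length(perts) == 0L || length(paths) == 0L) {
    empty <- data.frame(perturbation = character(0), target_gene = character(0),
                        pathway = character(0), score = numeric(0),
                        n_genes_used = integer(0), p_value = numeric(0),
                        bf_p_value = numeric(0), neg_log10_p = numeric(0),
                        significant = logical(0), stringsAsFactors = FALSE)
    return(structure(empty, alpha = alpha, adjust = adjust,
                     control = coll$control_name,
                     class = c("activation_table", "data.frame")))
  }
  tg <- m$pert_meta$target_gene[match(perts, m$pert_meta$perturbation)]
  n_fail <- 0L
  rows <- vector("list", length(perts) * length(paths))
  k <- 0L
  cz <- m$z[perts, ctrl$genes, drop = FALSE]
  for (s in paths) {
    sz <- m$z[perts, s$genes, drop = FALSE]
    for (i in seq_along(perts)) {
      k <- k + 1L
      res <- tryCatch({
        x <- sz[i, ]; y <- cz[i, ]
        w <- .welch2(x, y)
        bf <- .brown_forsythe(c(x, y),
                              rep(c("s", "c"), c(length(x), length(y))))
        list(score = mean(x), p = w$p.value, bf = bf$p.value)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1L
        res <- list(score = NA_real_, p = NA_real_, bf = NA_real_)
      }
      rows[[k]] <- data.frame(
        perturbation = perts[i], target_gene = tg[i], pathway = s$name,
        score = res$score, n_genes_used = length(s$genes),
        p_value = res$p, bf_p_value = res$bf, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (n_fail) warning("activation_table: ", n_fail, " row(s) failed; ",
                      "scores/p-values set to NA")
  if (!identical(adjust, "none"))
    tab$p_value <- stats::ave(tab$p_value, tab$pathway,
                              FUN = function(p) stats::p.adjust(p, adjust))
  tab$neg_log10_p <- -log10(tab$p_value)
  tab$significant <- !is.na(tab$p_value) & tab$p_value < alpha
  rownames(tab) <- NULL
  structure(tab, alpha = alpha, adjust = adjust,
            control = coll$control_name,
            class = c("activation_table", "data.frame"))
}

#' @export
print.activation_table <- function(x, ...) {
  cat("<activation_table> ", nrow(x), " (perturbation, pathway) rows; alpha = ",
      attr(x, "alpha"), ", adjust = ", attr(x, "adjust"),
      ", control = ", attr(x, "control"), "\n", sep = "")
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
    if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.activation_table <- function(object, ...) {
  df <- as.data.frame(object)
  if (!nrow(df)) return(data.frame())
  out <- do.call(rbind, lapply(split(df, df$pathway), function(d) data.frame(
    pathway = d$pathway[1], n = nrow(d),
    n_significant = sum(d$significant, na.rm = TRUE),
    frac_significant = mean(d$significant, na.rm = TRUE),
    mean_score = mean(d$score, na.rm = TRUE),
    max_score = max(d$score, na.rm = TRUE), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.activation_table <- function(x, ...) {
  class(x) <- "data.frame"
  attr(x, "alpha") <- attr(x, "adjust") <- attr(x, "control") <- NULL
  x
}

#' @describeIn activation_table Export as TSV with the fixed column order
#'   `perturbation, target_gene, pathway, score, n_genes_used, p_value,
#'   bf_p_value, neg_log10_p, significant`.
#' @param tab An `activation_table`.
#' @param path Output TSV path.
#' @export
write_activation_table <- function(tab, path) {
  stopifnot(inherits(tab, "activation_table"))
  cols <- c("perturbation", "target_gene", "pathway", "score", "n_genes_used",
            "p_value", "bf_p_value", "neg_log10_p", "significant")
  df <- as.data.frame(tab)[, cols]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pathway activation versus knockdown efficiency
#'
#' Stress-pathway activation in CRISPRi screens is expected to reflect the
#' biology of the depleted target more than the depth of its depletion; this
#' helper quantifies that by correlating, per pathway, the activation score
#' with the perturbation's fraction knockdown (Pearson). Perturbations with
#' missing knockdown metadata are excluded with a logged count; fewer than 3
#' usable pairs, or zero score variance, yields an undefined (flagged)
#' result rather than an error.
#'
#' @param tab An [activation_table()].
#' @param m The [perturbation_matrix()] the table was computed from.
#' @return data.frame with columns `pathway`, `r`, `p_value`, `n`, `note`.
#' @export
correlate_knockdown <- function(tab, m) {
  stopifnot(inherits(tab, "activation_table"),
            inherits(m, "perturbation_matrix"))
  df <- as.data.frame(tab)
  kd <- m$pert_meta$knockdown_fraction[match(df$perturbation,
                                             m$pert_meta$perturbation)]
  df$kd <- kd
  n_missing <- sum(is.na(kd))
  if (n_missing)
    message("correlate_knockdown: excluding ", n_missing,
            " row(s) with missing knockdown_fraction")
  out <- do.call(rbind, lapply(split(df, df$pathway), function(d) {
    ok <- stats::complete.cases(d$score, d$kd)
    n <- sum(ok)
    if (n < 3L)
      return(data.frame(pathway = d$pathway[1], r = NA_real_,
                        p_value = NA_real_, n = n,
                        note = "fewer than 3 usable pairs",
                        stringsAsFactors = FALSE))
    if (stats::sd(d$score[ok]) == 0 || stats::sd(d$kd[ok]) == 0)
      return(data.frame(pathway = d$pathway[1], r = NA_real_,
                        p_value = NA_real_, n = n, note = "zero variance",
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(d$score[ok], d$kd[ok], method = "pearson")
    data.frame(pathway = d$pathway[1], r = unname(ct$estimate),
               p_value = ct$p.value, n = n, note = "",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
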
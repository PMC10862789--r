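# resolve a perturbation argument to a named per-gene z vector
.resolve_profile <- function(m, p, what = "perturbation") {
  if (inherits(p, "group_profile")) return(unclass(p))
  if (is.character(p) && length(p) == 1L) {
    if (!p %in% rownames(m$z)) stop("unknown ", what, ": ", p)
    return(m$z[p, ])
  }
  if (is.numeric(p)) {
    if (length(p) != ncol(m$z))
      stop(what, " vector length (", length(p),
           ") does not match panel size (", ncol(m$z), ")")
    if (is.null(names(p))) names(p) <- colnames(m$z)
    return(p[colnames(m$z)])
  }
  stop(what, " must be a perturbation id, a numeric per-gene vector, ",
       "or a group_profile")
}

.profile_label <- function(p, default) {
  if (inherits(p, "group_profile")) attr(p, "label")
  else if (is.character(p) && length(p) == 1L) p
  else default
}

#' Select genes responding to either of two perturbations
#'
#' Union filter used before perturbation-pair regression: keep genes whose
#' absolute z-score strictly exceeds `threshold` in either perturbation.
#' The returned list follows panel order. Raising the threshold can only
#' remove genes (antitone), and an empty result is allowed.
#'
#' @param m A [perturbation_matrix()].
#' @param pert_a,pert_b Perturbation identifiers (or per-gene z vectors /
#'   [group_profile()]s).
#' @param threshold Non-negative |z| cutoff; default 0.5, the conventional
#'   cutoff for "responding" transcripts in pseudobulk z-score data.
#' @return Character vector of gene symbols in panel order.
#' @export
filter_by_z <- function(m, pert_a, pert_b, threshold = 0.5) {
  stopifnot(inherits(m, "perturbation_matrix"), threshold >= 0)
  za <- .resolve_profile(m, pert_a, "pert_a")
  zb <- .resolve_profile(m, pert_b, "pert_b")
  colnames(m$z)[abs(za) > threshold | abs(zb) > threshold]
}

#' Perturbation-pair transcriptome regression
#'
#' Ordinary least-squares fit of one perturbation's z-scores on another's,
#' over the genes passing the |z| union filter (or an explicit gene list).
#' The first-named perturbation is the explanatory axis; the headline
#' statistic, R-squared, is orientation-free. A zero-variance explanatory
#' axis yields a flagged, undefined fit rather than an error.
#'
#' @param m A [perturbation_matrix()].
#' @param pert_x,pert_y Perturbation identifiers, per-gene z vectors, or
#'   [group_profile()]s. `pert_x` is the explanatory axis.
#' @param genes Optional explicit gene list; when `NULL`, [filter_by_z()]
#'   with `threshold` is applied.
#' @param threshold Passed to [filter_by_z()] when `genes` is `NULL`.
#' @return An object of class `"pert_regression"`: list with `pert_x`,
#'   `pert_y`, `slope`, `intercept`, `r2`, `n_genes`, `threshold`,
#'   `defined`, and the fitted point coordinates `x`, `y`.
#' @export
regress_perturbations <- function(m, pert_x, pert_y, genes = NULL,
                                  threshold = 0.5) {
  stopifnot(inherits(m, "perturbation_matrix"))
  zx <- .resolve_profile(m, pert_x, "pert_x")
  zy <- .resolve_profile(m, pert_y, "pert_y")
  if (is.null(genes)) genes <- filter_by_z(m, zx, zy, threshold)
  else {
    genes <- toupper(genes)
    miss <- setdiff(genes, colnames(m$z))
    if (length(miss)) stop("gene(s) not in panel: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    threshold <- NA_real_
  }
  out <- list(pert_x = .profile_label(pert_x, "x"),
              pert_y = .profile_label(pert_y, "y"),
              slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
              n_genes = length(genes), threshold = threshold,
              defined = FALSE, x = zx[genes], y = zy[genes])
  if (length(genes) < 2L) {
    warning("fewer than 2 genes pass the filter; fit undefined")
    return(structure(out, class = "pert_regression"))
  }
  if (stats::var(out$x) == 0) {
    warning("explanatory axis has zero variance; fit undefined")
    return(structure(out, class = "pert_regression"))
  }
  fit <- stats::lm(y ~ x, data = list(x = out$x, y = out$y))
  out$slope <- unname(stats::coef(fit)[2])
  out$intercept <- unname(stats::coef(fit)[1])
  # a perfect fit (e.g. self-comparison) is legitimate here, not suspect
  out$r2 <- suppressWarnings(summary(fit)$r.squared)
  out$defined <- TRUE
  structure(out, class = "pert_regression")
}

#' @export
print.pert_regression <- function(x, ...) {
  cat("<pert_regression> ", x$pert_y, " ~ ", x$pert_x, "\n", sep = "")
  if (!is.na(x$threshold))
    cat("  filter: |z| > ", x$threshold, " in either perturbation\n", sep = "")
  cat("  n_genes = ", x$n_genes, "\n", sep = "")
  if (x$defined)
    cat(sprintf("  slope = %.4f, intercept = %.4f, R2 = %.4f\n",
                x$slope, x$intercept, x$r2))
  else cat("  fit undefined\n")
  invisible(x)
}

#' @export
coef.pert_regression <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
plot.pert_regression <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("grey30", 0.6),
                 xlab = paste0(x$pert_x, " (z)"),
                 ylab = paste0(x$pert_y, " (z)"), ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  if (x$defined) {
    graphics::abline(x$intercept, x$slope, col = "firebrick", lwd = 2)
    graphics::mtext(sprintf("R2 = %.3f (n = %d)", x$r2, x$n_genes),
                    side = 3, adj = 1, cex = 0.8)
  }
  invisible(x)
}

#' Average a group of perturbations into one profile
#'
#' Gene-wise arithmetic mean of z across member perturbations — used to
#' compare, e.g., the pooled transcriptional footprint of several EIF2B
#' subunit depletions against a single mitochondrial chaperone depletion.
#'
#' @param m A [perturbation_matrix()].
#' @param perts Member perturbation identifiers (>= 1).
#' @param label Name for the grouped profile.
#' @return Named numeric vector of class `"group_profile"` (per-gene mean z),
#'   with attribute `label`.
#' @export
group_profile <- function(m, perts, label = paste(perts, collapse = "+")) {
  stopifnot(inherits(m, "perturbation_matrix"))
  if (length(perts) == 0L) stop("group is empty")
  bad <- setdiff(perts, rownames(m$z))
  if (length(bad)) stop("unknown perturbation(s): ", paste(bad, collapse = ", "))
  v <- colMeans(m$z[perts, , drop = FALSE])
  structure(v, label = label, n_members = length(perts),
            class = "group_profile")
}

#' @export
print.group_profile <- function(x, ...) {
  cat("<group_profile> '", attr(x, "label"), "': ", attr(x, "n_members"),
      " perturbation(s), ", length(x), " genes\n", sep = "")
  invisible(x)
}

#' Contrast a flagged gene class between two perturbations
#'
#' Summarizes, for each perturbation, the mean z inside versus outside a
#' flagged gene class (e.g. mtDNA-encoded transcripts), and the
#' between-perturbation difference of the within-class means — the statistic
#' that exposes, for instance, a selective depletion of mtDNA-encoded genes
#' under mitochondrial (but not cytosolic) ISR-inducing perturbations.
#'
#' @param m A [perturbation_matrix()] with the class annotated (see
#'   [annotate_gene_classes()]).
#' @param pert_a,pert_b Perturbation identifiers or profiles.
#' @param class_flag Name of a logical column of `gene_meta`.
#' @return A list of class `"gene_class_contrast"`: `per_perturbation`
#'   (data.frame with `perturbation`, `mean_in_class`, `mean_out_class`,
#'   `difference`), `between` (within-class mean of a minus b), `n_class`,
#'   `class_flag`.
#' @export
compare_gene_class <- function(m, pert_a, pert_b,
                               class_flag = "mtdna_encoded") {
  stopifnot(inherits(m, "perturbation_matrix"))
  flags <- names(m$gene_meta)[vapply(m$gene_meta, is.logical, logical(1))]
  if (!class_flag %in% names(m$gene_meta))
    stop("gene class '", class_flag, "' is not annotated; available flags: ",
         if (length(flags)) paste(flags, collapse = ", ") else "(none)")
  inc <- m$gene_meta[[class_flag]]
  if (!any(inc)) stop("gene class '", class_flag, "' flags no genes")
  za <- .resolve_profile(m, pert_a, "pert_a")
  zb <- .resolve_profile(m, pert_b, "pert_b")
  la <- .profile_label(pert_a, "a"); lb <- .profile_label(pert_b, "b")
  per <- data.frame(
    perturbation = c(la, lb),
    mean_in_class = c(mean(za[inc]), mean(zb[inc])),
    mean_out_class = c(mean(za[!inc]), mean(zb[!inc])),
    stringsAsFactors = FALSE)
  per$difference <- per$mean_in_class - per$mean_out_class
  structure(list(per_perturbation = per,
                 between = mean(za[inc]) - mean(zb[inc]),
                 n_class = sum(inc), class_flag = class_flag),
            class = "gene_class_contrast")
}

#' @export
print.gene_class_contrast <- function(x, ...) {
  cat("<gene_class_contrast> flag '", x$class_flag, "' (", x$n_class,
      " genes)\n", sep = "")
  print.data.frame(x$per_perturbation, digits = 4)
  cat(sprintf("  between-perturbation within-class difference: %.4f\n",
              x$between))
  invisible(x)
}

#' Principal component analysis of perturbation profiles
#'
#' PCA of the perturbations x genes z matrix (observations are
#' perturbations) via [stats::prcomp()]. Genes are mean-centred by default
#' and not variance-scaled, matching the convention for z-score input whose
#' scale is already comparable across genes. Variance fractions come from
#' the squared singular values and are non-negative, non-increasing, and sum
#' to one; component signs are arbitrary.
#'
#' @param m A [perturbation_matrix()].
#' @param perts Perturbations to include (default all).
#' @param center,scale. Passed to [stats::prcomp()].
#' @return Object of class `"pert_pca"`: `component_scores`
#'   (perturbation x component), `loadings` (gene x component),
#'   `variance_fractions`, `center`, `scale`, `degenerate` flag.
#' @export
pca_perturbations <- function(m, perts = NULL, center = TRUE, scale. = FALSE) {
  stopifnot(inherits(m, "perturbation_matrix"))
  if (is.null(perts)) perts <- perturbations(m)
  if (length(perts) < 2L || ncol(m$z) < 2L)
    stop("PCA needs >= 2 perturbations and >= 2 genes")
  zz <- m$z[perts, , drop = FALSE]
  total_var <- sum(apply(zz, 2, stats::var))
  if (total_var == 0) {
    warning("constant matrix: variance fractions undefined")
    return(structure(list(component_scores = NULL, loadings = NULL,
                          variance_fractions = NA_real_, center = center,
                          scale = scale., degenerate = TRUE),
                     class = "pert_pca"))
  }
  pc <- stats::prcomp(zz, center = center, scale. = scale.)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(component_scores = pc$x, loadings = pc$rotation,
                 variance_fractions = vf, center = center, scale = scale.,
                 degenerate = FALSE),
            class = "pert_pca")
}

#' @export
print.pert_pca <- function(x, ...) {
  if (x$degenerate) {
    cat("<pert_pca> degenerate (constant input)\n")
    return(invisible(x))
  }
  cat("<pert_pca> ", nrow(x$component_scores), " perturbations, ",
      length(x$variance_fractions), " components\n", sep = "")
  vf <- utils::head(x$variance_fractions, 5)
  cat("  variance fractions: ",
      paste(sprintf("PC%d %.1f%%", seq_along(vf), 100 * vf), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.pert_pca <- function(x, components = c(1, 2), col = "grey30", ...) {
  if (x$degenerate) stop("degenerate PCA cannot be plotted")
  s <- x$component_scores
  vf <- x$variance_fractions
  graphics::plot(s[, components[1]], s[, components[2]], pch = 16, col = col,
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                100 * vf[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                100 * vf[components[2]]), ...)
  graphics::abline(h = 0, v = 0, col = "grey85")
  invisible(x)
}

#' @describeIn pca_perturbations Export scores, loadings and variance
#'   fractions as a TSV trio rooted at `stem`.
#' @param x A `pert_pca` object.
#' @param stem Output stem.
#' @export
write_pca <- function(x, stem) {
  stopifnot(inherits(x, "pert_pca"), !x$degenerate)
  ws <- function(mat, path, id) {
    df <- data.frame(id = rownames(mat), stringsAsFactors = FALSE)
    names(df) <- id
    df <- cbind(df, as.data.frame(mat))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ws(x$component_scores, paste0(stem, ".scores.tsv"), "perturbation")
  ws(x$loadings, paste0(stem, ".loadings.tsv"), "gene")
  utils::write.table(
    data.frame(component = seq_along(x$variance_fractions),
               variance_fraction = x$variance_fractions),
    paste0(stem, ".variance.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(paste0(stem, c(".scores.tsv", ".loadings.tsv", ".variance.tsv")))
}
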
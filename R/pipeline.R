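#' Run configuration
#'
#' A single validated document describing one analysis run; serialized as
#' JSON next to the outputs so every run is reproducible from its own
#' record. Unspecified fields take the documented defaults.
#'
#' @param input TSV stem of a pseudobulk dataset (see [read_pseudobulk()]),
#'   or `NULL` to simulate.
#' @param dialect Input dialect, `"tsv"` or `"h5ad"`.
#' @param genesets Path to a GMT file; `NULL` uses the packaged panels.
#' @param control Control set name override.
#' @param targets Optional character vector restricting perturbations by
#'   target gene, or path to a factor-list TSV.
#' @param alpha Significance level.
#' @param adjust Multiple-testing method (`"none"` or a
#'   [stats::p.adjust()] method).
#' @param z_threshold |z| cutoff for pair regression.
#' @param compare Optional list of 2-element character vectors: perturbation
#'   pairs to regress.
#' @param pca Logical: run PCA over the (selected) perturbations.
#' @param simulate Logical: when `input` is `NULL`, simulate the default
#'   synthetic study.
#' @param plots Logical: write SVG volcano/heatmap alongside the TSVs.
#' @param seed Integer seed (used for simulation).
#' @param outdir Output directory.
#' @return Object of class `"run_config"` (a validated list).
#' @export
run_config <- function(input = NULL, dialect = "tsv", genesets = NULL,
                       control = NULL, targets = NULL, alpha = 0.05,
                       adjust = "none", z_threshold = 0.5, compare = NULL,
                       pca = FALSE, simulate = is.null(input), plots = TRUE,
                       seed = 1, outdir = tempfile("perturbstress_run")) {
  stopifnot(alpha > 0, alpha < 1, z_threshold >= 0)
  if (is.null(input) && !simulate)
    stop("config needs either an input dataset or simulate = TRUE")
  if (!is.null(compare)) {
    stopifnot(is.list(compare),
              all(vapply(compare, length, integer(1)) == 2L))
  }
  structure(list(input = input, dialect = dialect, genesets = genesets,
                 control = control, targets = targets, alpha = alpha,
                 adjust = adjust, z_threshold = z_threshold,
                 compare = compare, pca = pca, simulate = simulate,
                 plots = plots, seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON path.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$compare)) {
    if (is.matrix(cfg$compare))
      cfg$compare <- lapply(seq_len(nrow(cfg$compare)),
                            function(i) cfg$compare[i, ])
    else if (!is.list(cfg$compare)) cfg$compare <- list(cfg$compare)
  }
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.log_line <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  writeLines(line, con)
}

#' Execute a configured analysis run
#'
#' Orchestrates the stages of the profiling pipeline as configured: acquire
#' the dataset (read or simulate), optionally restrict to curated targets,
#' score every perturbation against every pathway, optionally regress
#' configured perturbation pairs and run PCA, and write every numeric
#' artifact as TSV (plots are derived views, never the only record),
#' together with the resolved configuration and a log recording the package
#' version, seed, input checksums and data dimensions.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of output paths plus the in-memory
#'   `activation_table` (`$scores`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  con <- file(log_path, "w")
  on.exit(close(con), add = TRUE)
  .log_line(con, "perturbstress ",
            as.character(utils::packageVersion("perturbstress")),
            ", seed ", config$seed)
  paths <- list(log = log_path)

  coll <- if (is.null(config$genesets)) stress_genesets()
          else parse_gmt(config$genesets)
  if (!is.null(config$control))
    coll <- geneset_collection(coll$sets, control_name = config$control)
  .log_line(con, "gene sets: ", length(coll$sets), " (control: ",
            coll$control_name, ")")

  if (!is.null(config$input)) {
    m <- read_pseudobulk(config$input, dialect = config$dialect)
    for (f in paste0(.tsv_stem(config$input),
                     c(".z.tsv", ".pert.tsv", ".gene.tsv")))
      if (file.exists(f))
        .log_line(con, "input ", basename(f), " md5 ", tools::md5sum(f))
    truth <- NULL
  } else {
    study <- simulate_study(synthetic_spec(genesets = coll,
                                           seed = config$seed))
    m <- study$matrix
    truth <- study$truth
    tp <- file.path(config$outdir, "truth.tsv")
    utils::write.table(truth, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$truth <- tp
    .log_line(con, "simulated default study, seed ", config$seed)
  }
  .log_line(con, "dataset: ", nrow(m$z), " perturbations x ", ncol(m$z),
            " genes")

  if (!is.null(config$targets)) {
    targets <- if (length(config$targets) == 1L &&
                   file.exists(config$targets))
      read_factor_list(config$targets) else config$targets
    m <- select_perturbations(m, targets)
    .log_line(con, "target selection: ", nrow(m$z), " perturbations kept, ",
              length(attr(m, "missing_targets")), " requested targets absent")
  }

  tab <- activation_table(m, coll, alpha = config$alpha,
                          adjust = config$adjust)
  sp <- file.path(config$outdir, "activation_scores.tsv")
  write_activation_table(tab, sp)
  paths$scores_tsv <- sp
  .log_line(con, "scored ", nrow(tab), " (perturbation, pathway) pairs; ",
            sum(tab$significant), " significant at alpha ", config$alpha)

  if (!is.null(config$compare)) {
    cmp <- do.call(rbind, lapply(config$compare, function(pair) {
      r <- regress_perturbations(m, pair[1], pair[2],
                                 threshold = config$z_threshold)
      data.frame(pert_x = r$pert_x, pert_y = r$pert_y, slope = r$slope,
                 intercept = r$intercept, r2 = r$r2, n_genes = r$n_genes,
                 threshold = r$threshold, stringsAsFactors = FALSE)
    }))
    cp <- file.path(config$outdir, "pair_regressions.tsv")
    utils::write.table(cmp, cp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$compare_tsv <- cp
    .log_line(con, "regressed ", nrow(cmp), " perturbation pair(s)")
  }

  if (isTRUE(config$pca)) {
    pc <- pca_perturbations(m)
    paths$pca_tsv <- write_pca(pc, file.path(config$outdir, "pca"))
    .log_line(con, "PCA: PC1 explains ",
              sprintf("%.1f%%", 100 * pc$variance_fractions[1]))
  }

  if (isTRUE(config$plots)) {
    vp <- file.path(config$outdir, "volcano.svg")
    grDevices::svg(vp, width = 7, height = 5)
    plot_volcano(tab)
    grDevices::dev.off()
    paths$volcano <- vp
    hp <- file.path(config$outdir, "heatmap.svg")
    grDevices::svg(hp, width = 8, height = 6)
    plot_heatmap(m, coll)
    grDevices::dev.off()
    paths$heatmap <- hp
  }

  cfgp <- file.path(config$outdir, "config.json")
  write_run_config(config, cfgp)
  paths$config <- cfgp
  .log_line(con, "done")
  invisible(c(paths, list(scores = tab)))
}

#' Pathway target-gene heatmap
#'
#' Draws the set-by-perturbation z-score heatmap: rows are target genes
#' grouped by pathway in gene-set file order, columns are perturbations
#' (optionally grouped), and the diverging palette is centred at z = 0.
#'
#' @param m A [perturbation_matrix()].
#' @param coll A [geneset_collection()] (control set excluded from rows).
#' @param perts Columns to draw; default all perturbations.
#' @param pert_groups Optional named list grouping perturbations into
#'   column blocks (e.g. factor sublists); order of the list drives column
#'   order.
#' @param zlim Symmetric colour range; default covers the data.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, a list with the drawn matrix (`z`, genes x
#'   perturbations), `row_order`, `col_order`, `row_pathway` and `breaks` —
#'   the numeric record of what the image shows.
#' @export
plot_heatmap <- function(m, coll, perts = NULL, pert_groups = NULL,
                         zlim = NULL, ...) {
  stopifnot(inherits(m, "perturbation_matrix"),
            inherits(coll, "geneset_collection"))
  mapped <- suppressMessages(suppressWarnings(
    map_to_panel(coll, panel_genes(m), min_fraction = 0.01)))
  sets <- pathway_sets(mapped)
  rows <- unname(unlist(lapply(sets, `[[`, "genes")))
  row_pathway <- rep(vapply(sets, `[[`, character(1), "name"),
                     vapply(sets, function(s) length(s$genes), integer(1)))
  dup <- duplicated(rows)  # arm sets repeat UPR members; keep first
  rows <- rows[!dup]; row_pathway <- row_pathway[!dup]
  cols <- if (!is.null(pert_groups)) unlist(pert_groups)
          else if (!is.null(perts)) perts else perturbations(m)
  cols <- cols[cols %in% perturbations(m)]
  if (!length(rows) || !length(cols)) stop("empty heatmap selection")
  zz <- t(m$z[cols, rows, drop = FALSE])  # genes x perturbations
  if (is.null(zlim)) zlim <- c(-1, 1) * max(abs(zz), 1e-9)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(255)
  breaks <- seq(zlim[1], zlim[2], length.out = 256)
  zc <- pmin(pmax(zz, zlim[1]), zlim[2])
  graphics::image(x = seq_len(ncol(zc)), y = seq_len(nrow(zc)),
                  z = t(zc)[, rev(seq_len(nrow(zc))), drop = FALSE],
                  col = pal, breaks = breaks, axes = FALSE,
                  xlab = "perturbation", ylab = "", ...)
  graphics::axis(2, at = rev(seq_len(nrow(zc))), labels = rownames(zc),
                 las = 2, cex.axis = 0.5, tick = FALSE)
  bnd <- cumsum(rle(row_pathway)$lengths)
  graphics::abline(h = nrow(zc) - bnd[-length(bnd)] + 0.5, col = "grey40")
  graphics::box()
  invisible(list(z = zz, row_order = rows, col_order = cols,
                 row_pathway = row_pathway, breaks = breaks,
                 midpoint = (breaks[128] + breaks[129]) / 2))
}

#' Volcano plot of pathway activation
#'
#' Activation score against -log10 p-value, one colour per pathway, with a
#' horizontal line at the configured significance level.
#'
#' @param tab An [activation_table()].
#' @param alpha Significance line; defaults to the table's alpha.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data.frame of plotted points (`pathway`, `x`,
#'   `y`).
#' @export
plot_volcano <- function(tab, alpha = attr(tab, "alpha"), ...) {
  stopifnot(inherits(tab, "activation_table"))
  df <- as.data.frame(tab)
  if (!nrow(df)) stop("empty activation table")
  pathways <- sort(unique(df$pathway))
  pal <- stats::setNames(
    grDevices::hcl.colors(max(3L, length(pathways)), "Dark 3")[
      seq_along(pathways)], pathways)
  x <- df$score; y <- df$neg_log10_p
  y[!is.finite(y)] <- max(y[is.finite(y)], 1) * 1.05
  graphics::plot(x, y, col = pal[df$pathway], pch = 16, cex = 0.6,
                 xlab = "pathway activation score (mean z)",
                 ylab = expression(-log[10] ~ p), ...)
  graphics::abline(h = -log10(alpha), lty = 2, col = "grey40")
  graphics::abline(v = 0, col = "grey85")
  graphics::legend("topleft", legend = pathways, col = pal, pch = 16,
                   bty = "n", cex = 0.8)
  invisible(data.frame(pathway = df$pathway, x = x, y = y,
                       stringsAsFactors = FALSE))
}
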
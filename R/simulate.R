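#' Perturbation program: the planted effects of one perturbation class
#'
#' A program describes what a class of simulated perturbations does on the
#' z scale: a mean shift \eqn{\delta} (in control-SD units) planted on each
#' named pathway gene set, an optional shift applied to all mtDNA-encoded
#' genes, and the Beta distribution its knockdown fractions are drawn from
#' (independent of effect size by default, giving the knockdown-independence
#' check a true null).
#'
#' @param shifts Named numeric vector mapping gene-set name to delta
#'   (may be empty for a null class).
#' @param mtdna_shift Shift applied to mtDNA-flagged genes (default 0).
#' @param knockdown Length-2 numeric `c(shape1, shape2)` for the Beta
#'   distribution of simulated knockdown fractions.
#' @return Object of class `"perturbation_program"`.
#' @export
perturbation_program <- function(shifts = numeric(0), mtdna_shift = 0,
                                 knockdown = c(shape1 = 5, shape2 = 2)) {
  if (length(shifts) && is.null(names(shifts)))
    stop("shifts must be named by gene set")
  stopifnot(is.numeric(mtdna_shift), length(mtdna_shift) == 1L,
            length(knockdown) == 2L, all(knockdown > 0))
  structure(list(shifts = shifts, mtdna_shift = mtdna_shift,
                 knockdown = knockdown),
            class = "perturbation_program")
}

#' Default perturbation classes
#'
#' The five effect classes plus a null class that together reproduce the
#' qualitative selectivity pattern of stress-pathway profiling in K562
#' CRISPRi screens:
#' \describe{
#'   \item{mito_like}{ISR delta = 1.5 with an mtDNA down-shift of -0.8
#'     (mitochondrial proteostasis factor depletion).}
#'   \item{er_like}{UPR delta = 1.5 plus a weak ISR delta = 0.5 (ER
#'     proteostasis factor depletion; the weak ISR component reflects the
#'     PERK arm shared between UPR and ISR).}
#'   \item{keap1_like}{OSR delta = 1.5 (loss of the NRF2 repressor).}
#'   \item{uba1_like}{HSR delta = 1.5 (proteasomal stress).}
#'   \item{eif2b_like}{ISR delta = 1.5 without mtDNA involvement (ISR
#'     induction through ternary-complex starvation).}
#'   \item{null}{no planted effects.}
#' }
#' Effect sizes are chosen to give high per-perturbation power with
#' 10-20-gene panels against a 19-gene control set at alpha = 0.05.
#'
#' @return Named list of [perturbation_program()]s.
#' @export
default_programs <- function() {
  list(
    mito_like = perturbation_program(c(ISR = 1.5), mtdna_shift = -0.8),
    er_like = perturbation_program(c(UPR = 1.5, ISR = 0.5)),
    keap1_like = perturbation_program(c(OSR = 1.5)),
    uba1_like = perturbation_program(c(HSR = 1.5)),
    eif2b_like = perturbation_program(c(ISR = 1.5)),
    null = perturbation_program())
}

#' Specification of a synthetic pseudobulk study
#'
#' Describes a full simulated dataset: panel size, perturbation classes and
#' their planted programs, noise level, gemgroup structure and seed. The
#' panel always contains every gene-set member, a designated block of
#' synthetic mtDNA-encoded genes (symbols with the standard `MT-` prefix,
#' disjoint from all gene sets), and anonymous filler genes up to
#' `n_genes`.
#'
#' @param genesets A [geneset_collection()]; defaults to the packaged
#'   stress-pathway panels.
#' @param classes Named list of [perturbation_program()]s; defaults to
#'   [default_programs()].
#' @param n_per_class Perturbations per class: a single count or a vector
#'   named by class. Default 60.
#' @param n_genes Total panel size (default 2000).
#' @param n_mtdna_genes Number of synthetic mtDNA-encoded genes (default 13,
#'   the number of protein-coding genes on the human mitochondrial genome).
#' @param noise_sd Per-gene z-scale noise SD (default 1, the null-model SD
#'   after control normalization).
#' @param module_cor Optional loading in \[0, 1) of a shared per-set latent
#'   factor (correlated-module mode); 0 = independent genes (default).
#' @param n_gemgroups Number of 10X gemgroups (default 4).
#' @param n_controls_per_gemgroup Control sgRNAs per gemgroup (default 50).
#' @param baseline_mean,baseline_sd Location/scale of raw per-gene baseline
#'   expression (arbitrary units; only the z scale matters downstream).
#' @param seed Integer RNG seed; fixed seed gives bit-reproducible output.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(genesets = stress_genesets(),
                           classes = default_programs(),
                           n_per_class = 60, n_genes = 2000,
                           n_mtdna_genes = 13, noise_sd = 1,
                           module_cor = 0, n_gemgroups = 4,
                           n_controls_per_gemgroup = 50,
                           baseline_mean = 10, baseline_sd = 2,
                           seed = 1) {
  stopifnot(inherits(genesets, "geneset_collection"), length(classes) > 0L,
            !is.null(names(classes)), noise_sd > 0,
            module_cor >= 0, module_cor < 1,
            n_gemgroups >= 1, n_controls_per_gemgroup >= 2)
  stopifnot(all(vapply(classes, inherits, logical(1), "perturbation_program")))
  set_genes <- unique(unlist(lapply(genesets$sets, `[[`, "genes")))
  for (cl in names(classes)) {
    unknown <- setdiff(names(classes[[cl]]$shifts), names(genesets$sets))
    if (length(unknown))
      stop("class '", cl, "' plants shifts on unknown gene set(s): ",
           paste(unknown, collapse = ", "))
  }
  mtdna <- if (n_mtdna_genes > 0)
    sprintf("MT-SYN%02d", seq_len(n_mtdna_genes)) else character(0)
  n_filler <- n_genes - length(set_genes) - length(mtdna)
  if (n_filler < 0)
    stop("n_genes too small: need at least ",
         length(set_genes) + length(mtdna), " genes for set members")
  panel <- c(set_genes, mtdna,
             if (n_filler > 0) sprintf("G%04d", seq_len(n_filler)))
  if (length(n_per_class) == 1L && is.null(names(n_per_class)))
    n_per_class <- stats::setNames(rep(n_per_class, length(classes)),
                                   names(classes))
  if (!setequal(names(n_per_class), names(classes)))
    stop("n_per_class names must match class names")
  n_per_class <- n_per_class[names(classes)]
  structure(list(genesets = genesets, classes = classes,
                 n_per_class = n_per_class, n_genes = n_genes,
                 gene_panel = panel, mtdna_genes = mtdna,
                 noise_sd = noise_sd, module_cor = module_cor,
                 n_gemgroups = n_gemgroups,
                 n_controls_per_gemgroup = n_controls_per_gemgroup,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", sum(x$n_per_class), " perturbations (",
      length(x$classes), " classes) x ", x$n_genes, " genes; seed ",
      x$seed, "\n", sep = "")
  for (cl in names(x$classes)) {
    pr <- x$classes[[cl]]
    sh <- if (length(pr$shifts))
      paste(names(pr$shifts), pr$shifts, sep = "=", collapse = ", ")
    else "none"
    cat(sprintf("  %-12s n=%3d  shifts: %s%s\n", cl, x$n_per_class[cl], sh,
                if (pr$mtdna_shift != 0)
                  sprintf("; mtDNA %+.2f", pr$mtdna_shift) else ""))
  }
  cat("  noise_sd ", x$noise_sd, ", ", x$n_gemgroups, " gemgroups x ",
      x$n_controls_per_gemgroup, " control sgRNAs\n", sep = "")
  invisible(x)
}

# deterministic (RNG-free) design: ids, classes, gemgroups, planted deltas
.study_design <- function(spec) {
  classes <- rep(names(spec$classes), spec$n_per_class)
  ids <- unlist(lapply(names(spec$classes), function(cl)
    sprintf("%s_%03d", toupper(cl), seq_len(spec$n_per_class[cl]))))
  n_pert <- length(ids)
  gemgroup <- rep_len(seq_len(spec$n_gemgroups), n_pert)
  delta <- matrix(0, n_pert, spec$n_genes,
                  dimnames = list(ids, spec$gene_panel))
  is_mt <- spec$gene_panel %in% spec$mtdna_genes
  for (cl in names(spec$classes)) {
    pr <- spec$classes[[cl]]
    rows <- classes == cl
    for (set_name in names(pr$shifts)) {
      g <- spec$genesets$sets[[set_name]]$genes
      delta[rows, g] <- delta[rows, g] + pr$shifts[[set_name]]
    }
    if (pr$mtdna_shift != 0 && any(is_mt))
      delta[rows, is_mt] <- delta[rows, is_mt] + pr$mtdna_shift
  }
  list(ids = ids, classes = classes, gemgroup = gemgroup, delta = delta)
}

# z-scale effect + noise for the perturbation block (shared by both modes);
# in correlated-module mode each gene set gets a per-perturbation latent
# factor with loading module_cor, idiosyncratic noise scaled to preserve
# the marginal SD.
.effect_noise <- function(spec, design) {
  n_pert <- length(design$ids)
  lambda <- spec$module_cor
  eps <- matrix(stats::rnorm(n_pert * spec$n_genes), n_pert, spec$n_genes)
  if (lambda > 0) {
    eps <- eps * sqrt(1 - lambda^2)
    for (s in spec$genesets$sets) {
      f <- stats::rnorm(n_pert)
      idx <- match(s$genes, spec$gene_panel)
      eps[, idx] <- eps[, idx] + lambda * f
    }
  }
  spec$noise_sd * (design$delta + eps)
}

.draw_knockdown <- function(spec, design) {
  kd <- numeric(length(design$ids))
  for (cl in names(spec$classes)) {
    rows <- design$classes == cl
    pars <- spec$classes[[cl]]$knockdown
    kd[rows] <- stats::rbeta(sum(rows), pars[1], pars[2])
  }
  kd
}

.truth_table <- function(spec, design, kd) {
  truth <- data.frame(perturbation = design$ids,
                      class_label = design$classes,
                      gemgroup = design$gemgroup,
                      knockdown_fraction = kd,
                      stringsAsFactors = FALSE)
  for (set_name in names(spec$genesets$sets)) {
    col <- paste0("delta_", set_name)
    truth[[col]] <- vapply(design$classes, function(cl) {
      sh <- spec$classes[[cl]]$shifts
      if (set_name %in% names(sh)) unname(sh[[set_name]]) else 0
    }, numeric(1))
  }
  truth$mtdna_shift <- vapply(design$classes, function(cl)
    spec$classes[[cl]]$mtdna_shift, numeric(1))
  rownames(truth) <- NULL
  truth
}

#' Simulate raw (un-normalized) pseudobulk expression
#'
#' Generates a raw expression table on an arbitrary measurement scale:
#' per-gene baselines, control sgRNA groups in every gemgroup (carrying no
#' planted effects), and perturbation sgRNAs whose planted z-scale effects
#' are injected in units of the per-gene control SD — so that
#' [z_normalize()] recovers them. Exists so the normalization step itself is
#' exercised end to end.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `"raw_pseudobulk"`: `values` (sgRNA x gene
#'   matrix), `meta` (per-sgRNA data.frame with `sgrna`, `gemgroup`,
#'   `is_control`, `class_label`, `knockdown_fraction`), `truth`, `spec`.
#' @export
simulate_raw <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_controls_per_gemgroup < 2L)
    stop("each gemgroup needs >= 2 control sgRNAs")
  set.seed(spec$seed)
  design <- .study_design(spec)
  mu <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
  sigma <- exp(stats::rnorm(spec$n_genes, 0, 0.25))
  kd <- .draw_knockdown(spec, design)
  ctrl_ids <- unlist(lapply(seq_len(spec$n_gemgroups), function(k)
    sprintf("CTRL_G%d_%03d", k, seq_len(spec$n_controls_per_gemgroup))))
  ctrl_gem <- rep(seq_len(spec$n_gemgroups),
                  each = spec$n_controls_per_gemgroup)
  n_ctrl <- length(ctrl_ids)
  ctrl_eff <- spec$noise_sd *
    matrix(stats::rnorm(n_ctrl * spec$n_genes), n_ctrl, spec$n_genes)
  pert_eff <- .effect_noise(spec, design)
  eff <- rbind(ctrl_eff, pert_eff)
  values <- sweep(sweep(eff, 2, sigma, "*"), 2, mu, "+")
  rownames(values) <- c(ctrl_ids, design$ids)
  colnames(values) <- spec$gene_panel
  meta <- data.frame(
    sgrna = rownames(values),
    gemgroup = c(ctrl_gem, design$gemgroup),
    is_control = rep(c(TRUE, FALSE), c(n_ctrl, length(design$ids))),
    class_label = c(rep("control", n_ctrl), design$classes),
    knockdown_fraction = c(rep(NA_real_, n_ctrl), kd),
    stringsAsFactors = FALSE)
  structure(list(values = values, meta = meta,
                 truth = .truth_table(spec, design, kd), spec = spec),
            class = "raw_pseudobulk")
}

#' Z-normalize raw pseudobulk expression against gemgroup controls
#'
#' For every gene within every gemgroup, expression is re-expressed as
#' standard deviations from the control sgRNA group of that gemgroup:
#' \eqn{z = (x - \bar{x}_{ctrl}) / s_{ctrl}}, with the sample SD (n-1
#' denominator) throughout. Re-normalizing the control group against itself
#' therefore yields exactly mean 0 and SD 1 per gene per gemgroup.
#'
#' @param raw A [simulate_raw()] result, or a plain sgRNA x gene numeric
#'   matrix (then `control_ids` and `gemgroups` are required).
#' @param control_ids Row names of control sgRNAs (matrix input only).
#' @param gemgroups Gemgroup assignment per row, named by row or in row
#'   order (matrix input only).
#' @param zero_sd Policy for genes with zero control SD in some gemgroup:
#'   `"drop"` the gene from the output panel (default) or set the affected
#'   `"zero"` entries to 0; either choice is logged.
#' @param include_controls Keep the (re-normalized) control sgRNAs as rows
#'   of the output matrix; default `FALSE`.
#' @return A [perturbation_matrix()].
#' @export
z_normalize <- function(raw, control_ids = NULL, gemgroups = NULL,
                        zero_sd = c("drop", "zero"),
                        include_controls = FALSE) {
  zero_sd <- match.arg(zero_sd)
  if (inherits(raw, "raw_pseudobulk")) {
    values <- raw$values
    control_ids <- raw$meta$sgrna[raw$meta$is_control]
    gemgroups <- stats::setNames(raw$meta$gemgroup, raw$meta$sgrna)
    meta <- raw$meta
  } else {
    stopifnot(is.matrix(raw), !is.null(rownames(raw)),
              !is.null(control_ids), !is.null(gemgroups))
    values <- raw
    if (is.null(names(gemgroups))) {
      stopifnot(length(gemgroups) == nrow(values))
      gemgroups <- stats::setNames(gemgroups, rownames(values))
    }
    meta <- data.frame(sgrna = rownames(values),
                       gemgroup = unname(gemgroups[rownames(values)]),
                       is_control = rownames(values) %in% control_ids,
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(control_ids %in% rownames(values)))
  z <- values
  drop_genes <- logical(ncol(values))
  for (k in unique(meta$gemgroup)) {
    rows_k <- meta$gemgroup == k
    ctrl_k <- meta$is_control & rows_k
    if (sum(ctrl_k) < 2L)
      stop("gemgroup ", k, " has fewer than 2 control sgRNAs")
    cm <- colMeans(values[ctrl_k, , drop = FALSE])
    cs <- apply(values[ctrl_k, , drop = FALSE], 2, stats::sd)
    zsd <- cs == 0
    cs[zsd] <- 1  # placeholder; affected entries handled by policy
    z[rows_k, ] <- sweep(sweep(values[rows_k, , drop = FALSE], 2, cm, "-"),
                         2, cs, "/")
    if (any(zsd)) {
      if (zero_sd == "drop") drop_genes <- drop_genes | zsd
      else z[rows_k, zsd] <- 0
    }
  }
  if (any(drop_genes))
    message("z_normalize: dropped ", sum(drop_genes),
            " gene(s) with zero control SD")
  z <- z[, !drop_genes, drop = FALSE]
  keep <- if (include_controls) meta$sgrna else meta$sgrna[!meta$is_control]
  z <- z[keep, , drop = FALSE]
  pm <- data.frame(perturbation = keep,
                   target_gene = keep,
                   stringsAsFactors = FALSE)
  extra <- intersect(c("knockdown_fraction", "class_label", "gemgroup"),
                     names(meta))
  for (col in extra)
    pm[[col]] <- meta[[col]][match(keep, meta$sgrna)]
  perturbation_matrix(z, pert_meta = pm)
}

#' Simulate a complete synthetic study
#'
#' Composes [simulate_raw()] and [z_normalize()] into a ready-to-score
#' [perturbation_matrix()] with its ground-truth table. The alternative
#' `scale = "z"` mode plants effects directly on the z scale
#' (z = delta + noise), the idealized model in which a null gene's z is
#' exactly standard normal — useful for calibration and effect-recovery
#' checks free of finite-control-group estimation noise.
#'
#' @param spec A [synthetic_spec()].
#' @param scale `"raw"` (default; simulate raw expression, then normalize)
#'   or `"z"` (plant directly on the z scale).
#' @return List of class `"synthetic_study"`: `matrix`
#'   (a [perturbation_matrix()]), `truth` (data.frame with one row per
#'   perturbation: class, per-set planted deltas, mtDNA shift, knockdown
#'   fraction, gemgroup), `spec`.
#' @export
simulate_study <- function(spec, scale = c("raw", "z")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  scale <- match.arg(scale)
  if (scale == "raw") {
    raw <- simulate_raw(spec)
    m <- z_normalize(raw)
  } else {
    set.seed(spec$seed)
    design <- .study_design(spec)
    kd <- .draw_knockdown(spec, design)
    z <- .effect_noise(spec, design)
    dimnames(z) <- dimnames(design$delta)
    pm <- data.frame(perturbation = design$ids, target_gene = design$ids,
                     knockdown_fraction = kd, class_label = design$classes,
                     gemgroup = design$gemgroup, stringsAsFactors = FALSE)
    m <- perturbation_matrix(z, pert_meta = pm)
    raw <- list(truth = .truth_table(spec, design, kd))
  }
  structure(list(matrix = m, truth = raw$truth, spec = spec),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> seed ", x$spec$seed, "\n", sep = "")
  print(x$matrix)
  cat("  classes: ", paste(sprintf("%s (%d)", names(table(x$truth$class_label)),
                                   table(x$truth$class_label)),
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}
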
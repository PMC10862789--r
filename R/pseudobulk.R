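#' Pseudobulk perturbation-by-gene z-score matrix
#'
#' The central data container: a dense perturbations x genes matrix of
#' z-normalized expression (each entry is the deviation of a gene's
#' pseudobulk expression in one CRISPRi perturbation from the mean of
#' control-sgRNA cells of the same gemgroup, in units of the control SD),
#' together with per-perturbation metadata (target gene, fraction knockdown,
#' optional class label) and per-gene metadata (mtDNA-encoded flag by
#' default).
#'
#' @param z Numeric matrix, perturbations in rows (rownames = perturbation
#'   ids), genes in columns (colnames = symbols).
#' @param pert_meta Optional data.frame with columns `perturbation`,
#'   `target_gene`, `knockdown_fraction` (in \[0, 1\] or `NA`) and optionally
#'   `class_label`. Defaults to `target_gene = perturbation`.
#' @param gene_meta Optional data.frame with columns `gene` and flag columns;
#'   an `mtdna_encoded` flag is derived from the standard human `MT-` symbol
#'   prefix when absent.
#' @param na_policy How to treat missing z values: `"error"` (default),
#'   `"zero"` (impute 0, logged), or `"drop"` (drop affected perturbation
#'   rows, logged).
#' @return An object of class `"perturbation_matrix"` with elements `z`,
#'   `pert_meta`, `gene_meta`.
#' @export
perturbation_matrix <- function(z, pert_meta = NULL, gene_meta = NULL,
                                na_policy = c("error", "zero", "drop")) {
  na_policy <- match.arg(na_policy)
  stopifnot(is.matrix(z), is.numeric(z))
  if (is.null(rownames(z)) || is.null(colnames(z)))
    stop("z must carry perturbation rownames and gene colnames")
  colnames(z) <- toupper(colnames(z))
  if (anyDuplicated(rownames(z))) stop("perturbation identifiers must be unique")
  if (anyDuplicated(colnames(z))) stop("gene symbols must be unique")
  if (anyNA(z)) {
    n_na <- sum(is.na(z))
    if (na_policy == "error")
      stop(n_na, " missing z value(s); set na_policy to 'zero' or 'drop'")
    if (na_policy == "zero") {
      z[is.na(z)] <- 0
      message("perturbation_matrix: imputed ", n_na, " missing z value(s) to 0")
    } else {
      bad <- rowSums(is.na(z)) > 0
      message("perturbation_matrix: dropped ", sum(bad),
              " perturbation(s) with missing z values")
      z <- z[!bad, , drop = FALSE]
    }
  }
  if (is.null(pert_meta)) {
    pert_meta <- data.frame(perturbation = rownames(z),
                            target_gene = rownames(z),
                            knockdown_fraction = NA_real_,
                            stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(pert_meta), "perturbation" %in% names(pert_meta))
  if (!"target_gene" %in% names(pert_meta))
    pert_meta$target_gene <- pert_meta$perturbation
  if (!"knockdown_fraction" %in% names(pert_meta))
    pert_meta$knockdown_fraction <- NA_real_
  if (nrow(pert_meta) != nrow(z) ||
      !setequal(pert_meta$perturbation, rownames(z)))
    stop("pert_meta rows (", nrow(pert_meta),
         ") do not match matrix perturbations (", nrow(z), ")")
  pert_meta <- pert_meta[match(rownames(z), pert_meta$perturbation), , drop = FALSE]
  kd <- pert_meta$knockdown_fraction
  if (any(!is.na(kd) & (kd < 0 | kd > 1)))
    stop("knockdown_fraction values must lie in [0, 1]")
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(gene = colnames(z),
                            mtdna_encoded = startsWith(colnames(z), "MT-"),
                            stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(gene_meta), "gene" %in% names(gene_meta))
  gene_meta$gene <- toupper(gene_meta$gene)
  if (nrow(gene_meta) != ncol(z) || !setequal(gene_meta$gene, colnames(z)))
    stop("gene_meta rows (", nrow(gene_meta),
         ") do not match matrix genes (", ncol(z), ")")
  gene_meta <- gene_meta[match(colnames(z), gene_meta$gene), , drop = FALSE]
  if (!"mtdna_encoded" %in% names(gene_meta))
    gene_meta$mtdna_encoded <- startsWith(gene_meta$gene, "MT-")
  rownames(pert_meta) <- rownames(gene_meta) <- NULL
  structure(list(z = z, pert_meta = pert_meta, gene_meta = gene_meta),
            class = "perturbation_matrix")
}

#' @export
print.perturbation_matrix <- function(x, ...) {
  kd <- x$pert_meta$knockdown_fraction
  cat("<perturbation_matrix> ", nrow(x$z), " perturbations x ",
      ncol(x$z), " genes\n", sep = "")
  cat("  knockdown_fraction missing: ",
      sprintf("%.1f%%", 100 * mean(is.na(kd))), "\n", sep = "")
  flags <- setdiff(names(x$gene_meta), "gene")
  for (f in flags)
    if (is.logical(x$gene_meta[[f]]))
      cat("  gene flag '", f, "': ", sum(x$gene_meta[[f]]), " genes\n", sep = "")
  invisible(x)
}

#' @export
dim.perturbation_matrix <- function(x) dim(x$z)

#' @rdname perturbation_matrix
#' @param m A `perturbation_matrix`.
#' @export
perturbations <- function(m) rownames(m$z)

#' @rdname perturbation_matrix
#' @export
panel_genes <- function(m) colnames(m$z)

# row subset preserving gene order and metadata alignment
.subset_perts <- function(m, keep) {
  perturbation_matrix(
    m$z[keep, , drop = FALSE],
    pert_meta = m$pert_meta[match(keep, m$pert_meta$perturbation), , drop = FALSE],
    gene_meta = m$gene_meta)
}

#' Read and write pseudobulk matrices
#'
#' Two on-disk dialects are supported. The TSV dialect is a three-file
#' sidecar layout rooted at a common stem: `<stem>.z.tsv` (first column
#' `perturbation`, remaining columns genes; values serialized with
#' full `%.17g` precision so write/read round-trips are bit-identical),
#' `<stem>.pert.tsv` and `<stem>.gene.tsv` for the metadata. The h5ad
#' dialect follows the AnnData HDF5 layout used by published pseudobulk
#' Perturb-seq resources: dense `X`, `obs/_index` plus per-column datasets
#' (including `fraction knockdown`), `var/_index`; it requires the
#' `rhdf5` package. Matrix orientation is sniffed against the length of the
#' per-observation metadata table and recorded in the load log, since
#' resource versions differ on whether perturbations are rows or columns.
#'
#' @param path TSV stem (or any of the three sidecar paths) for
#'   `dialect = "tsv"`; an `.h5ad` file for `dialect = "h5ad"`.
#' @param dialect `"tsv"` or `"h5ad"`.
#' @param na_policy Passed to [perturbation_matrix()].
#' @return A [perturbation_matrix()].
#' @export
read_pseudobulk <- function(path, dialect = c("tsv", "h5ad"),
                            na_policy = c("error", "zero", "drop")) {
  dialect <- match.arg(dialect)
  m <- switch(dialect,
              tsv = .read_pseudobulk_tsv(path, na_policy),
              h5ad = .read_pseudobulk_h5ad(path, na_policy))
  kd <- m$pert_meta$knockdown_fraction
  message("read_pseudobulk: ", nrow(m$z), " perturbations x ", ncol(m$z),
          " genes (", dialect, "); knockdown_fraction missing for ",
          sum(is.na(kd)), " perturbation(s)")
  m
}

.tsv_stem <- function(path) sub("[.](z|pert|gene)[.]tsv$", "", path)

.read_pseudobulk_tsv <- function(path, na_policy) {
  stem <- .tsv_stem(path)
  zf <- paste0(stem, ".z.tsv")
  pf <- paste0(stem, ".pert.tsv")
  gf <- paste0(stem, ".gene.tsv")
  for (f in c(zf, pf, gf)) if (!file.exists(f)) stop("missing file: ", f)
  zt <- utils::read.delim(zf, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(zt)[1] != "perturbation")
    stop("first column of ", zf, " must be 'perturbation'")
  z <- as.matrix(zt[, -1, drop = FALSE])
  rownames(z) <- zt$perturbation
  pert_meta <- utils::read.delim(pf, stringsAsFactors = FALSE)
  gene_meta <- utils::read.delim(gf, stringsAsFactors = FALSE)
  if (nrow(pert_meta) != nrow(z))
    stop("metadata table has ", nrow(pert_meta), " rows but matrix has ",
         nrow(z), " perturbations")
  perturbation_matrix(z, pert_meta, gene_meta, na_policy = na_policy)
}

#' @rdname read_pseudobulk
#' @param m A [perturbation_matrix()] to serialize.
#' @param stem Output stem for the TSV sidecar trio.
#' @export
write_pseudobulk <- function(m, stem) {
  stopifnot(inherits(m, "perturbation_matrix"))
  zt <- data.frame(perturbation = rownames(m$z), stringsAsFactors = FALSE,
                   check.names = FALSE)
  zv <- apply(m$z, 2, function(col) sprintf("%.17g", col))
  zt <- cbind(zt, as.data.frame(zv, stringsAsFactors = FALSE,
                                check.names = FALSE))
  utils::write.table(zt, paste0(stem, ".z.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$pert_meta, paste0(stem, ".pert.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(m$gene_meta, paste0(stem, ".gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paste0(stem, c(".z.tsv", ".pert.tsv", ".gene.tsv")))
}

.h5_read_index <- function(file, group) {
  idx <- tryCatch(rhdf5::h5read(file, paste0(group, "/_index")),
                  error = function(e) NULL)
  if (is.null(idx))
    idx <- tryCatch(rhdf5::h5read(file, paste0(group, "/index")),
                    error = function(e) NULL)
  as.character(idx)
}

.read_pseudobulk_h5ad <- function(path, na_policy) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading .h5ad requires the 'rhdf5' package")
  stopifnot(file.exists(path))
  X <- rhdf5::h5read(path, "X")
  obs_idx <- .h5_read_index(path, "obs")
  var_idx <- .h5_read_index(path, "var")
  if (!length(obs_idx) || !length(var_idx))
    stop("h5ad file lacks obs/var index datasets")
  X <- as.matrix(X)
  # orientation sniff: observations (perturbations) define the obs index
  if (nrow(X) == length(obs_idx) && ncol(X) == length(var_idx)) {
    orient <- "obs-rows"
  } else if (nrow(X) == length(var_idx) && ncol(X) == length(obs_idx)) {
    X <- t(X)
    orient <- "obs-columns (transposed on load)"
  } else {
    stop("matrix shape ", nrow(X), "x", ncol(X),
         " matches neither obs (", length(obs_idx), ") nor var (",
         length(var_idx), ") layout")
  }
  message("read_pseudobulk: h5ad orientation = ", orient)
  rownames(X) <- obs_idx
  colnames(X) <- var_idx
  obs_cols <- tryCatch(rhdf5::h5ls(path), error = function(e) NULL)
  pert_meta <- data.frame(perturbation = obs_idx, stringsAsFactors = FALSE)
  read_obs <- function(name) tryCatch(
    as.vector(rhdf5::h5read(path, paste0("obs/", name))),
    error = function(e) NULL)
  kd <- read_obs("fraction knockdown")
  if (!is.null(kd)) pert_meta$knockdown_fraction <- as.numeric(kd)
  tg <- read_obs("target_gene")
  if (!is.null(tg)) pert_meta$target_gene <- as.character(tg)
  cl <- read_obs("class_label")
  if (!is.null(cl)) pert_meta$class_label <- as.character(cl)
  perturbation_matrix(X, pert_meta, gene_meta = NULL, na_policy = na_policy)
}

#' @rdname read_pseudobulk
#' @export
write_pseudobulk_h5ad <- function(m, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("writing .h5ad requires the 'rhdf5' package")
  stopifnot(inherits(m, "perturbation_matrix"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(unname(m$z), path, "X")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(m$pert_meta$perturbation, path, "obs/_index")
  rhdf5::h5write(m$pert_meta$knockdown_fraction, path, "obs/fraction knockdown")
  rhdf5::h5write(m$pert_meta$target_gene, path, "obs/target_gene")
  if ("class_label" %in% names(m$pert_meta))
    rhdf5::h5write(m$pert_meta$class_label, path, "obs/class_label")
  rhdf5::h5write(colnames(m$z), path, "var/_index")
  rhdf5::H5close()
  invisible(path)
}

#' Subset a matrix to perturbations targeting a curated gene list
#'
#' Keeps only perturbations whose `target_gene` belongs to `targets`
#' (a character vector or a [read_factor_list()] table), reporting which
#' requested targets are absent from the screen — curated inventories
#' routinely include genes the published dataset did not retain.
#'
#' Gene order is never changed; the retained z rows equal direct row-slicing
#' of the original matrix.
#'
#' @param m A [perturbation_matrix()].
#' @param targets Character vector of target symbols, or a `factor_list`.
#' @return The subset matrix, with attribute `missing_targets` listing
#'   requested symbols absent from the screen.
#' @export
select_perturbations <- function(m, targets) {
  stopifnot(inherits(m, "perturbation_matrix"))
  if (inherits(targets, "factor_list") || is.data.frame(targets))
    targets <- targets$gene
  targets <- toupper(as.character(targets))
  if (length(targets) == 0L) stop("targets must be non-empty")
  targets <- unique(targets)
  present <- toupper(m$pert_meta$target_gene) %in% targets
  if (!any(present))
    stop("no perturbation in the matrix targets any of the ",
         length(targets), " requested genes")
  missing <- setdiff(targets, toupper(m$pert_meta$target_gene))
  out <- .subset_perts(m, rownames(m$z)[present])
  if (length(missing))
    message("select_perturbations: ", length(missing),
            " requested target(s) absent from the screen")
  attr(out, "missing_targets") <- missing
  out
}

#' Flag a class of genes in the panel metadata
#'
#' Adds (or overwrites) a boolean per-gene flag, e.g. marking the
#' mtDNA-encoded transcripts whose selective depletion distinguishes
#' mitochondrial proteostasis perturbations from other ISR inducers.
#'
#' @param m A [perturbation_matrix()].
#' @param class_name Name for the flag column in `gene_meta`.
#' @param members Character vector of gene symbols in the class.
#' @param overwrite Allow replacing an existing flag of the same name.
#' @return The annotated matrix.
#' @export
annotate_gene_classes <- function(m, class_name, members, overwrite = FALSE) {
  stopifnot(inherits(m, "perturbation_matrix"),
            is.character(class_name), length(class_name) == 1L)
  if (class_name %in% names(m$gene_meta) && !overwrite)
    stop("gene class '", class_name,
         "' already annotated; use overwrite = TRUE")
  members <- toupper(members)
  flag <- m$gene_meta$gene %in% members
  if (!any(flag))
    warning("annotate_gene_classes: no member of '", class_name,
            "' is present in the panel")
  m$gene_meta[[class_name]] <- flag
  message("annotate_gene_classes: flagged ", sum(flag), " gene(s) as '",
          class_name, "'")
  m
}
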
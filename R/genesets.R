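#' Stress-pathway gene sets and collections
#'
#' A `geneset` is a named, ordered panel of gene symbols reporting on one
#' stress-responsive signaling pathway (or serving as the stable control
#' panel). A `geneset_collection` bundles several sets together with a
#' designated control set, the null reference group for all significance
#' testing downstream.
#'
#' Gene symbols are normalized to uppercase on construction and matched by
#' exact string equality thereafter; no aliasing is attempted. Gene order
#' within a set is preserved from the source file, so heatmap row order is
#' reproducible.
#'
#' @param name Short identifier for the set.
#' @param genes Character vector of gene symbols (non-empty, no duplicates
#'   after case normalization).
#' @param pathway_label One of `"UPR"`, `"ISR"`, `"HSR"`, `"OSR"`, `"ATF6"`,
#'   `"IRE1_XBP1s"`, `"CONTROL"` or `"custom"`. Defaults to the name itself
#'   when the name is a known label, otherwise `"custom"`.
#' @param source Free-text provenance note.
#' @return An object of class `"geneset"`.
#' @seealso [parse_gmt()], [geneset_collection()], [map_to_panel()]
#' @export
geneset <- function(name, genes, pathway_label = NULL, source = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  genes <- toupper(trimws(as.character(genes)))
  if (anyDuplicated(genes))
    stop("gene set '", name, "' contains duplicate symbols after case ",
         "normalization: ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  known <- c("UPR", "ISR", "HSR", "OSR", "ATF6", "IRE1_XBP1S", "CONTROL")
  if (is.null(pathway_label)) {
    pathway_label <- if (toupper(name) %in% known) toupper(name) else "custom"
    if (pathway_label == "IRE1_XBP1S") pathway_label <- "IRE1_XBP1s"
  }
  structure(list(name = name, pathway_label = pathway_label,
                 genes = genes, source = source),
            class = "geneset")
}

#' @export
print.geneset <- function(x, ...) {
  cat("<geneset> ", x$name, " [", x$pathway_label, "], ",
      length(x$genes), " genes\n", sep = "")
  cat("  ", paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.geneset <- function(x) length(x$genes)

#' Bundle gene sets into a collection with a designated control set
#'
#' @param sets A list of [geneset()] objects (names taken from the sets).
#' @param control_name Name of the member set to use as the control panel.
#'   Defaults to the unique set labelled `CONTROL` if there is one.
#' @return An object of class `"geneset_collection"`.
#' @export
geneset_collection <- function(sets, control_name = NULL) {
  stopifnot(is.list(sets), length(sets) > 0L)
  stopifnot(all(vapply(sets, inherits, logical(1), "geneset")))
  nm <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate set names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  ctrl_labelled <- nm[vapply(sets, function(s) s$pathway_label == "CONTROL", logical(1))]
  if (is.null(control_name)) {
    if (length(ctrl_labelled) == 1L) control_name <- ctrl_labelled
    else if (length(ctrl_labelled) > 1L)
      stop("multiple sets labelled CONTROL: ", paste(ctrl_labelled, collapse = ", "))
  }
  if (!is.null(control_name) && !control_name %in% nm)
    stop("control set '", control_name, "' is not a member of the collection")
  structure(list(sets = sets, control_name = control_name),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("<geneset_collection> ", length(x$sets), " sets",
      if (!is.null(x$control_name)) paste0(" (control: ", x$control_name, ")"),
      "\n", sep = "")
  for (s in x$sets)
    cat(sprintf("  %-12s %-10s %3d genes\n", s$name, s$pathway_label,
                length(s$genes)))
  invisible(x)
}

#' @export
length.geneset_collection <- function(x) length(x$sets)

#' @rdname geneset_collection
#' @param x A `geneset_collection`.
#' @export
control_set <- function(x) {
  stopifnot(inherits(x, "geneset_collection"))
  if (is.null(x$control_name)) stop("collection has no designated control set")
  x$sets[[x$control_name]]
}

#' @rdname geneset_collection
#' @export
pathway_sets <- function(x) {
  stopifnot(inherits(x, "geneset_collection"))
  x$sets[setdiff(names(x$sets), x$control_name)]
}

#' Parse gene sets from GMT text
#'
#' Reads the Broad GMT dialect: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Symbols are uppercased;
#' the order of genes within a line is preserved.
#'
#' @param path Path to a GMT file, or a character vector of GMT lines via
#'   `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @param control_name Control set designation; by default the set whose
#'   name (case-insensitively) equals `CONTROL`.
#' @return A [geneset_collection()].
#' @examples
#' coll <- parse_gmt(text = c("ISR\tsrc\tA\tB\tC", "CONTROL\tsrc\tD\tE"))
#' length(coll$sets$ISR$genes)  # 3
#' @export
parse_gmt <- function(path = NULL, text = NULL, control_name = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path), file.exists(path))
    text <- readLines(path, warn = FALSE)
  }
  text <- text[nzchar(trimws(text))]
  if (length(text) == 0L) stop("GMT input is empty")
  sets <- vector("list", length(text))
  for (i in seq_along(text)) {
    f <- strsplit(text[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, " ('", substr(text[[i]], 1, 30),
           "') has fewer than one gene")
    sets[[i]] <- geneset(name = f[1], genes = f[-(1:2)], source = f[2])
  }
  nm <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate set names in GMT input: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (is.null(control_name)) {
    hit <- nm[toupper(nm) == "CONTROL"]
    if (length(hit) == 1L) control_name <- hit
  }
  geneset_collection(sets, control_name = control_name)
}

#' @rdname parse_gmt
#' @param coll A `geneset_collection` to serialize.
#' @param path Output path; when `NULL` the GMT lines are returned invisibly.
#' @export
write_gmt <- function(coll, path = NULL) {
  stopifnot(inherits(coll, "geneset_collection"))
  lines <- vapply(coll$sets, function(s)
    paste(c(s$name, if (nzchar(s$source)) s$source else "na", s$genes),
          collapse = "\t"), character(1))
  if (!is.null(path)) writeLines(lines, path)
  invisible(unname(lines))
}

#' Validate a gene-set collection
#'
#' Report-only check of the collection invariants: the control set must not
#' share genes with any pathway set, and symbols within a set must be unique.
#' The caller decides how severe any violation is.
#'
#' @param coll A [geneset_collection()].
#' @return A list with `sizes` (named integer vector), `overlaps`
#'   (data.frame of control/pathway overlaps, one row per offending pair) and
#'   `violations` (character vector, empty iff the collection is valid).
#' @export
validate_collection <- function(coll) {
  stopifnot(inherits(coll, "geneset_collection"))
  sizes <- vapply(coll$sets, function(s) length(s$genes), integer(1))
  violations <- character(0)
  overlaps <- data.frame(set = character(0), n_shared = integer(0),
                         shared = character(0), stringsAsFactors = FALSE)
  if (is.null(coll$control_name)) {
    violations <- c(violations, "no designated control set")
  } else {
    ctrl <- control_set(coll)$genes
    for (s in pathway_sets(coll)) {
      shared <- intersect(ctrl, s$genes)
      if (length(shared)) {
        overlaps <- rbind(overlaps, data.frame(
          set = s$name, n_shared = length(shared),
          shared = paste(shared, collapse = ","), stringsAsFactors = FALSE))
        violations <- c(violations, paste0(
          "control set shares ", length(shared), " gene(s) with '", s$name, "'"))
      }
    }
  }
  list(sizes = sizes, overlaps = overlaps, violations = violations,
       valid = length(violations) == 0L)
}

#' Restrict a collection to the measured gene panel
#'
#' Pseudobulk screens quantify only a subset of the transcriptome, so each
#' gene set must be restricted to the measured panel before scoring. Coverage
#' (mapped / set size) is recorded per set; sets falling below
#' `min_fraction` are flagged with a warning, and a set with zero mapped
#' genes is a hard error.
#'
#' Mapping is idempotent and coverage is monotone in the panel: enlarging
#' the panel can never lower a set's coverage.
#'
#' @param coll A [geneset_collection()].
#' @param panel Character vector of measured gene symbols.
#' @param min_fraction Minimum acceptable coverage in (0, 1]; default 0.5.
#' @return The mapped collection, with a `coverage` attribute: a data.frame
#'   (`set`, `n_set`, `n_mapped`, `coverage`, `flagged`). Retrieve it with
#'   [set_coverage()].
#' @export
map_to_panel <- function(coll, panel, min_fraction = 0.5) {
  stopifnot(inherits(coll, "geneset_collection"), length(panel) > 0L)
  stopifnot(min_fraction > 0, min_fraction <= 1)
  panel <- toupper(panel)
  mapped <- coll
  cov <- data.frame(set = names(coll$sets),
                    n_set = NA_integer_, n_mapped = NA_integer_,
                    coverage = NA_real_, flagged = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(coll$sets)) {
    s <- coll$sets[[i]]
    keep <- s$genes[s$genes %in% panel]   # panel restriction, set order kept
    if (length(keep) == 0L)
      stop("gene set '", s$name, "' has no genes in the measured panel")
    mapped$sets[[i]]$genes <- keep
    cov$n_set[i] <- length(s$genes)
    cov$n_mapped[i] <- length(keep)
    cov$coverage[i] <- length(keep) / length(s$genes)
    cov$flagged[i] <- cov$coverage[i] < min_fraction
  }
  if (any(cov$flagged))
    warning("gene set(s) below min_fraction coverage: ",
            paste(cov$set[cov$flagged], collapse = ", "))
  low <- cov$coverage < 1
  if (any(low))
    message("map_to_panel: ", sum(cov$n_set - cov$n_mapped),
            " gene(s) absent from panel across ", sum(low), " set(s)")
  attr(mapped, "coverage") <- cov
  mapped
}

#' @rdname map_to_panel
#' @export
set_coverage <- function(coll) attr(coll, "coverage")

#' Packaged stress-pathway gene sets
#'
#' Loads the curated reference panels shipped with the package: target-gene
#' sets for the ISR (13 genes, ATF4-driven), the UPR (20 genes, the union of
#' its ATF6 and IRE1/XBP1s arms, 10 genes each), the HSR (12 HSF1 targets),
#' the OSR (12 NRF2 targets), and a control panel of 19 genes with stable
#' expression across insults.
#'
#' @param arms If `TRUE` (default) the ATF6 and IRE1/XBP1s arm sets are
#'   included alongside the combined UPR set.
#' @return A [geneset_collection()].
#' @export
stress_genesets <- function(arms = TRUE) {
  path <- system.file("extdata", "stress_genesets.gmt",
                      package = "perturbstress", mustWork = TRUE)
  coll <- parse_gmt(path)
  if (!arms)
    coll <- geneset_collection(
      coll$sets[setdiff(names(coll$sets), c("ATF6", "IRE1_XBP1s"))],
      control_name = coll$control_name)
  coll
}

#' Read a factor list (curated perturbation-target inventory)
#'
#' Factor lists enumerate proteostasis machinery (chaperones, proteases,
#' import and targeting factors) per organelle and drive perturbation
#' selection. Dialect: TSV with columns `list_name`, `sublist`, `gene`.
#'
#' @param path TSV path.
#' @param list_name Optional filter on the `list_name` column.
#' @return A data.frame of class `"factor_list"` with columns `list_name`,
#'   `sublist`, `gene` (symbols uppercased, unique within a list).
#' @export
read_factor_list <- function(path, list_name = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("list_name", "sublist", "gene")
  if (!all(need %in% names(df)))
    stop("factor list must have columns: ", paste(need, collapse = ", "))
  df$gene <- toupper(trimws(df$gene))
  if (!is.null(list_name)) df <- df[df$list_name %in% list_name, , drop = FALSE]
  if (nrow(df) == 0L) stop("factor list selection is empty")
  dup <- duplicated(df[c("list_name", "gene")])
  if (any(dup)) {
    message("read_factor_list: dropping ", sum(dup), " duplicate member(s)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("factor_list", "data.frame")
  df
}
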
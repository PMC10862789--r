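# In-code fixtures shared across test files.

toy_collection <- function() {
  geneset_collection(list(
    geneset("ISR", c("A1", "A2", "A3")),
    geneset("UPR", c("B1", "B2", "B3", "B4")),
    geneset("CONTROL", c("C1", "C2", "C3"))))
}

# perturbation_matrix from an explicit matrix (rows auto-named P1.. if bare)
toy_matrix <- function(z, ...) {
  if (is.null(rownames(z))) rownames(z) <- paste0("P", seq_len(nrow(z)))
  if (is.null(colnames(z))) colnames(z) <- paste0("G", seq_len(ncol(z)))
  perturbation_matrix(z, ...)
}

# a small deterministic matrix whose panel covers toy_collection
toy_study_matrix <- function(n_pert = 4, seed = 1) {
  set.seed(seed)
  genes <- c("A1", "A2", "A3", "B1", "B2", "B3", "B4", "C1", "C2", "C3",
             "MT-X1", "MT-X2", "X1", "X2")
  z <- matrix(rnorm(n_pert * length(genes)), n_pert, length(genes),
              dimnames = list(paste0("P", seq_len(n_pert)), genes))
  perturbation_matrix(z)
}

# a fast ISR + control spec for calibration-style runs
small_calibration_collection <- function() {
  full <- stress_genesets(arms = FALSE)
  geneset_collection(full$sets[c("ISR", "CONTROL")],
                     control_name = "CONTROL")
}
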
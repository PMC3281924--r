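# Independent brute-force oracles used to verify the package's statistics.
# These deliberately use the most literal formulation available, never the
# code paths they check.

# Step-up FDR by definition: q_i = min over j with rank >= rank_i of m p_(j)/j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  qs <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    qs[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- qs
  out
}

# Generic Pearson chi-square: sum over cells of (O - E)^2 / E.
oracle_chisq_2x2 <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Pearson correlation by direct summation.
oracle_pcc <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Position-by-position IUPAC scan of one strand.
oracle_scan_strand <- function(seq, pattern, classes) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  w <- length(p)
  if (length(s) < w) return(0L)
  hits <- 0L
  for (i in seq_len(length(s) - w + 1L)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!s[i + j - 1L] %in% classes[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

oracle_scan <- function(seq, pattern, revcomp_fun, classes) {
  oracle_scan_strand(seq, pattern, classes) +
    oracle_scan_strand(seq, revcomp_fun(pattern), classes)
}

# IUPAC matching classes mirroring the documented convention (pattern N also
# matches a literal N in the sequence).
oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

# Reverse complement for the oracle, written independently.
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

random_iupac_pattern <- function(len) {
  paste(sample(names(oracle_iupac), len, replace = TRUE,
               prob = c(rep(4, 4), rep(2, 6), rep(1, 4), 1)), collapse = "")
}

random_dna <- function(len, with_n = FALSE) {
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Tiny labelled matrix for hand-checkable cases.
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  values
}

toy_design <- function(samples, tissue, stage = NA_integer_, replicate = NULL,
                       treatment = "control") {
  if (is.null(replicate)) replicate <- seq_along(samples)
  validate_sample_design(tibble::tibble(
    sample_id = samples, tissue = tissue, stage = stage,
    replicate = replicate, treatment = treatment
  ))
}

place_like_library <- function() {
  motif_library(c(
    ABRE = "ACGTGKC", GCN4 = "TGAGTCA", PYRIMIDINE = "CCTTTT",
    RY = "CATGCA", GT1 = "GRWAAW", CAAT = "CCAAT", EBOX = "CANNTG",
    SKN1 = "GTCAT"
  ))
}
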
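# IUPAC nucleotide ambiguity classes over {A,C,G,T}. By convention the
# pattern letter N additionally matches a literal N in the subject sequence;
# an N in the sequence matches no other pattern letter (conservative
# non-match for masked genome positions).
iupac_classes <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

# Reverse complement for IUPAC pattern strings (and plain ACGTN sequences).
revcomp <- function(x) {
  flipped <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Translate an IUPAC pattern to a POSIX character-class regex.
iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(iupac_classes))
  if (length(bad)) {
    stop("illegal IUPAC character(s) in pattern '", pattern, "': ",
         paste(unique(bad), collapse = ""), call. = FALSE)
  }
  paste(vapply(chars, function(ch) {
    cls <- iupac_classes[[ch]]
    if (length(cls) == 1) cls else paste0("[", paste(cls, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Draw one concrete ACGT instance of an IUPAC pattern (for motif planting).
instantiate_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    cls <- setdiff(iupac_classes[[ch]], "N")
    if (length(cls) == 1) cls else sample(cls, 1)
  }, character(1)), collapse = "")
}

# Per-position match probability of an IUPAC pattern against i.i.d.
# background with the given GC content (used for closed-form hit
# expectations in tests and documentation).
iupac_match_prob <- function(pattern, gc = 0.5) {
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2, N = 0)
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  prod(vapply(chars, function(ch) sum(base_p[iupac_classes[[ch]]]), numeric(1)))
}
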
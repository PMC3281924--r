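#' Extract upstream (promoter) regions from a genome and gene models
#'
#' For a plus-strand gene whose translation start sits at genomic position
#' `s`, the promoter is bases `[max(1, s - L), s - 1]` in genomic
#' orientation; for a minus-strand gene ending at `e` it is the reverse
#' complement of `[e + 1, min(contig end, e + L)]`. Regions are truncated
#' only at contig boundaries ("up to L nt" semantics; neighbouring genes do
#' not clip), and are reported 5'->3' on the gene's sense strand so motif
#' positions read biologically. Coordinates are GFF3 1-based inclusive. The
#' translation start is the CDS start when CDS features are present for a
#' gene, else the gene feature boundary. Genes with a zero-length promoter
#' (at a contig edge) are skipped with a warning; a gene on an unknown
#' contig is an error.
#'
#' @param genome FASTA path, or a named character vector / DNAStringSet of
#'   contig sequences.
#' @param models GFF3 path, or a tibble with GFF3 columns (`seqid`, `type`,
#'   `start`, `end`, `strand`, `attributes`).
#' @param upstream Maximum promoter length L in nt (default 3000).
#' @return Tibble of class `promoter_set`: `gene`, `contig`, `start`,
#'   `end`, `strand`, `seq`.
#' @export
extract_upstream <- function(genome, models, upstream = 3000) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome),
                              sub("\\s.*$", "", names(genome)))
  }
  genome <- toupper(genome)
  models <- read_gene_models(models)
  genes <- models[models$type == "gene", ]
  if (!nrow(genes)) stop("no gene features in the models", call. = FALSE)
  gene_ids <- gff_attribute(genes$attributes, "ID")
  cds <- models[models$type == "CDS", ]
  if (nrow(cds)) {
    parent <- gff_attribute(cds$attributes, "Parent")
    cds_start <- tapply(cds$start, parent, min)
    cds_end <- tapply(cds$end, parent, max)
  }

  rows <- vector("list", nrow(genes))
  skipped <- character(0)
  for (i in seq_len(nrow(genes))) {
    ctg <- genes$seqid[i]
    if (!ctg %in% names(genome)) stop("gene on unknown contig: ", ctg, call. = FALSE)
    len <- nchar(genome[[ctg]])
    id <- gene_ids[i]
    s <- genes$start[i]
    e <- genes$end[i]
    if (nrow(cds) && id %in% names(cds_start)) {
      if (genes$strand[i] == "+") s <- cds_start[[id]] else e <- cds_end[[id]]
    }
    if (genes$strand[i] == "+") {
      from <- max(1, s - upstream)
      to <- s - 1
      if (to < from) { skipped <- c(skipped, id); next }
      seq <- substr(genome[[ctg]], from, to)
    } else {
      from <- e + 1
      to <- min(len, e + upstream)
      if (to < from) { skipped <- c(skipped, id); next }
      seq <- revcomp(substr(genome[[ctg]], from, to))
    }
    rows[[i]] <- tibble::tibble(gene = id, contig = ctg, start = from, end = to,
                                strand = genes$strand[i], seq = seq)
  }
  if (length(skipped)) {
    warning("zero-length promoter, gene(s) skipped: ", paste(skipped, collapse = ", "))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("promoter_set", class(out))
  out
}

# Load gene models from a GFF3 path (via rtracklayer) or pass a tibble
# through unchanged.
read_gene_models <- function(models) {
  if (is.data.frame(models)) return(tibble::as_tibble(models))
  gr <- rtracklayer::import(models, format = "gff3")
  md <- as.data.frame(gr)
  attrs <- paste0("ID=", if ("ID" %in% names(md)) md$ID else NA)
  if ("Parent" %in% names(md)) {
    par <- vapply(md$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
                  character(1))
    attrs <- ifelse(is.na(par), attrs, paste0(attrs, ";Parent=", par))
  }
  tibble::tibble(
    seqid = as.character(md$seqnames),
    type = as.character(md$type),
    start = md$start,
    end = md$end,
    strand = as.character(md$strand),
    attributes = attrs
  )
}

gff_attribute <- function(attributes, key) {
  hit <- regmatches(attributes,
                    regexpr(paste0("(^|;)", key, "=[^;]*"), attributes))
  out <- rep(NA_character_, length(attributes))
  found <- grepl(paste0("(^|;)", key, "="), attributes)
  out[found] <- sub(paste0("^;?", key, "="), "", hit)
  out
}

#' Scan promoters for IUPAC motif occurrences on both strands
#'
#' Counts every position (overlapping occurrences included) where all IUPAC
#' classes of the pattern match, on the promoter and its reverse complement
#' (implemented by also scanning the reverse-complemented pattern).
#' `N` in a sequence matches only the pattern letter `N`. Presence means
#' count >= 1.
#'
#' @param proms A `promoter_set` tibble from [extract_upstream()], or a
#'   named character vector of promoter sequences.
#' @param lib A [motif_library()].
#' @return Tibble of class `motif_hits`: `gene`, `motif`, `count`,
#'   `present`, `positions` (number of scanned windows across both
#'   strands, used by occurrence-mode enrichment).
#' @export
scan_motifs <- function(proms, lib) {
  if (is.data.frame(proms)) {
    seqs <- stats::setNames(proms$seq, proms$gene)
  } else {
    seqs <- proms
  }
  if (is.null(names(seqs))) stop("promoters must be named by gene", call. = FALSE)
  seqs <- toupper(seqs)
  lib <- motif_library(lib)
  count_overlapping <- function(regex, x) {
    hits <- gregexpr(paste0("(?=", regex, ")"), x, perl = TRUE)
    vapply(hits, function(h) if (h[1] == -1) 0L else length(h), integer(1))
  }
  rows <- purrr::map2(lib$motif_id, lib$pattern, function(id, pat) {
    fw <- iupac_to_regex(pat)
    rc <- iupac_to_regex(revcomp(pat))
    cnt <- count_overlapping(fw, seqs) + count_overlapping(rc, seqs)
    w <- nchar(pat)
    tibble::tibble(gene = names(seqs), motif = id, count = cnt,
                   present = cnt >= 1,
                   positions = 2L * pmax(nchar(seqs) - w + 1L, 0L))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("motif_hits", class(out))
  out
}

#' Cis-element enrichment of a gene group against a promoter universe
#'
#' Default (presence) mode compares, motif by motif, the fraction of group
#' genes whose promoter contains at least one occurrence with the fraction
#' in the whole universe, by the same 2x2 chi-square as category
#' enrichment, with BH-FDR across the motif library and an enriched call at
#' `q < fdr`. Occurrence mode uses total occurrence counts over total
#' scanned windows instead. Motifs absent from the entire universe are
#' skipped with a warning.
#'
#' @param hits `motif_hits` from [scan_motifs()], covering the universe.
#' @param group Gene-id vector, a subset of `universe`.
#' @param universe Gene-id vector.
#' @param mode `"presence"` (default) or `"occurrences"`.
#' @param fdr Enrichment FDR threshold (default 0.05).
#' @return Tibble of class `enrichment_result` with an extra
#'   `enriched_call` column (`q < fdr` and over-represented).
#' @export
motif_enrichment <- function(hits, group, universe, mode = c("presence", "occurrences"),
                             fdr = 0.05) {
  mode <- match.arg(mode)
  group <- unique(group)
  universe <- unique(universe)
  if (!all(group %in% universe)) stop("group must be a subset of the universe", call. = FALSE)
  h <- hits[hits$gene %in% universe, ]
  rows <- lapply(split(h, h$motif), function(hm) {
    in_group <- hm$gene %in% group
    if (mode == "presence") {
      a <- sum(hm$present[in_group])
      K <- sum(hm$present)
      n <- length(group)
      N <- length(universe)
    } else {
      a <- sum(hm$count[in_group])
      K <- sum(hm$count)
      n <- sum(hm$positions[in_group])
      N <- sum(hm$positions)
    }
    if (K == 0) {
      warning("motif '", hm$motif[1], "' absent from the universe, skipped")
      return(NULL)
    }
    b <- n - a
    cc <- K - a
    d <- N - n - cc
    chi2 <- chisq_2x2(a, b, cc, d)
    p <- max(stats::pchisq(chi2, df = 1, lower.tail = FALSE), .Machine$double.xmin)
    tibble::tibble(term = hm$motif[1], label = hm$motif[1], a = a, n = n, K = K, N = N,
                   chi2 = chi2, p = p, neglog10p = -log10(p),
                   expected_low = min_expected_2x2(a, b, cc, d) < 5,
                   enriched = a / n > K / N)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) stop("no scannable motifs in the universe", call. = FALSE)
  out$q <- bh_fdr(out$p)
  out$enriched_call <- out$enriched & out$q < fdr
  out <- out[, c("term", "label", "a", "n", "K", "N", "chi2", "p", "neglog10p",
                 "q", "expected_low", "enriched", "enriched_call")]
  class(out) <- c("enrichment_result", class(out))
  out
}
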
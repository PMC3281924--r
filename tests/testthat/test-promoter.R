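test_that("upstream extraction follows the coordinate conventions", {
  # 10 kb contig; plus-strand gene with translation start at 5001
  contig <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  genome <- c(chr1 = contig)
  models <- tibble::tibble(
    seqid = "chr1", source = ".", type = "gene",
    start = c(5001L, 1001L, 2001L), end = c(6000L, 1500L, 4000L),
    score = ".", strand = c("+", "+", "-"), phase = ".",
    attributes = c("ID=gPlus", "ID=gEdge", "ID=gMinus")
  )
  proms <- extract_upstream(genome, models, upstream = 3000)

  p1 <- proms[proms$gene == "gPlus", ]
  expect_equal(nchar(p1$seq), 3000)
  expect_identical(p1$seq, substr(contig, 2001, 5000))

  # truncation at the contig start: "up to 3000" semantics
  p2 <- proms[proms$gene == "gEdge", ]
  expect_equal(nchar(p2$seq), 1000)
  expect_identical(p2$seq, substr(contig, 1, 1000))

  # minus-strand gene ending at 4000: reverse complement of 4001..7000,
  # first promoter base = complement of base 7000
  p3 <- proms[proms$gene == "gMinus", ]
  expect_equal(nchar(p3$seq), 3000)
  expect_identical(substr(p3$seq, 1, 1),
                   chartr("ACGT", "TGCA", substr(contig, 7000, 7000)))
  expect_identical(p3$seq, oracle_revcomp(substr(contig, 4001, 7000)))

  bad <- models[1, ]
  bad$seqid <- "chrX"
  expect_error(extract_upstream(genome, bad, 100), "unknown contig")

  edge <- models[1, ]
  edge$start <- 1L
  expect_warning(out <- extract_upstream(genome, edge, 100), "skipped")
  expect_identical(nrow(out), 0L)
})

test_that("CDS features override the gene boundary as translation start", {
  contig <- paste(rep(c("A", "C", "G", "T"), 250), collapse = "")
  genome <- c(chr1 = contig)
  models <- tibble::tibble(
    seqid = "chr1", source = ".", type = c("gene", "CDS"),
    start = c(101L, 151L), end = c(600L, 300L), score = ".",
    strand = "+", phase = ".",
    attributes = c("ID=g1", "ID=g1.cds;Parent=g1")
  )
  proms <- extract_upstream(genome, models, upstream = 50)
  expect_identical(proms$seq, substr(contig, 101, 150))
})

test_that("GFF3 written by the simulator re-imports through rtracklayer", {
  lib <- place_like_library()
  pp <- simulate_promoters(n_genes = 30, length = 200, motifs = lib,
                           group_size = 10, seed = 17)
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome_fasta(pp$genome, fa)
  write_gff3(pp$models, gff)
  proms <- extract_upstream(fa, gff, upstream = 200)
  expect_identical(stats::setNames(proms$seq, proms$gene)[names(pp$promoters)],
                   pp$promoters)
})

test_that("motif scanning is strand-aware and counts overlaps", {
  lib <- motif_library(c(M = "TGTAAAG"))
  seqs <- c(fw = paste0("CCCCC", "TGTAAAG", "CCCCC"),
            rc = paste0("CCCCC", "CTTTACA", "CCCCC"),
            none = "CCCCCCCCCCCCCCCCC")
  hits <- scan_motifs(seqs, lib)
  expect_identical(hits$count[hits$gene == "fw"], 1L)
  expect_true(hits$present[hits$gene == "rc"])
  expect_false(hits$present[hits$gene == "none"])

  # overlapping occurrences all counted (AAAA in AAAAAA: 3 per strand? no -
  # forward 3 and reverse complement TTTT 0)
  lib2 <- motif_library(c(P = "AAAA"))
  h2 <- scan_motifs(c(x = "AAAAAA"), lib2)
  expect_identical(h2$count, 3L)

  # pattern N matches a literal N, other classes do not
  lib3 <- motif_library(c(P = "CANTG"))
  h3 <- scan_motifs(c(a = "GGCANTGGG", b = "GGCAATGGG"), lib3)
  expect_true(all(h3$present))
  lib4 <- motif_library(c(P = "CARTG"))
  h4 <- scan_motifs(c(a = "GGCANTGGG"), lib4)
  expect_false(h4$present)

  expect_error(motif_library(c(P = "AC-GT")), "illegal|pattern")
})

test_that("scanning equals the position-by-position oracle on random inputs", {
  set.seed(17)
  for (i in 1:100) {
    seq <- random_dna(200, with_n = (i %% 5 == 0))
    pat <- random_iupac_pattern(sample(4:9, 1))
    lib <- motif_library(stats::setNames(pat, "P"))
    got <- scan_motifs(stats::setNames(seq, "g"), lib)$count
    expect_identical(got,
                     as.integer(oracle_scan(seq, pat, oracle_revcomp, oracle_iupac)),
                     info = paste(pat, "on", substr(seq, 1, 20)))
  }
})

test_that("presence indicators are strand-symmetric", {
  set.seed(17)
  lib <- place_like_library()
  seqs <- stats::setNames(replicate(30, random_dna(150)), sprintf("g%02d", 1:30))
  fwd <- scan_motifs(seqs, lib)
  rev <- scan_motifs(stats::setNames(vapply(seqs, oracle_revcomp, character(1)),
                                     names(seqs)), lib)
  ord <- order(fwd$gene, fwd$motif)
  expect_identical(fwd$present[ord], rev$present[order(rev$gene, rev$motif)])
  expect_identical(fwd$count[ord], rev$count[order(rev$gene, rev$motif)])
})

test_that("motif enrichment shares the contingency arithmetic and guards", {
  # presence in 30/100 group genes vs 100/1000 universe genes reproduces the
  # canonical 49.38 chi-square
  universe <- sprintf("g%04d", 1:1000)
  group <- universe[1:100]
  present <- c(universe[1:30], universe[101:170])
  hits <- tibble::tibble(gene = universe, motif = "M",
                         count = as.integer(universe %in% present),
                         present = universe %in% present,
                         positions = 2L * 994L)
  res <- motif_enrichment(hits, group, universe)
  expect_equal(res$chi2, 49.3827, tolerance = 1e-4)
  expect_true(res$enriched)

  # group == universe: no contrast
  res0 <- motif_enrichment(hits, universe, universe)
  expect_equal(res0$chi2, 0)
  expect_false(res0$enriched_call)

  absent_hits <- hits
  absent_hits$present <- FALSE
  absent_hits$count <- 0L
  expect_warning(expect_error(motif_enrichment(absent_hits, group, universe),
                              "no scannable"),
                 "absent from the universe")
})

test_that("a planted motif is called enriched against the genome background", {
  lib <- place_like_library()
  pp <- simulate_promoters(n_genes = 1000, length = 500, motifs = lib,
                           group_size = 100, target_fraction_in_group = 0.4,
                           background_fraction = 0.05, seed = 17)
  hits <- scan_motifs(pp$promoters, lib)
  res <- motif_enrichment(hits, pp$truth$group, names(pp$promoters))
  planted <- res[res$term == pp$truth$planted_motif, ]
  expect_true(planted$enriched_call)
  expect_lt(planted$q, 0.05)
})
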
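test_that("the compendium simulator is deterministic and keeps its books", {
  cfg <- sim_config(n_genes = 1000)
  a <- simulate_compendium(cfg, seed = 17)
  b <- simulate_compendium(cfg, seed = 17)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth$predominant, b$truth$predominant)

  # exactly round(frac * n) genes per planted class
  cfg2 <- sim_config(n_genes = 1000, frac_absent = 0.10)
  tr <- simulate_compendium(cfg2, seed = 3)$truth
  expect_length(tr$absent, 100)
  expect_length(intersect(tr$absent, tr$expressed), 0)

  expect_error(sim_config(frac_absent = 0.9, frac_embryo = 0.2), "sum")
  expect_error(sim_config(effect_predominant = -1), "positive")
})

test_that("planted predominance effects are recovered on the raw scale", {
  sim <- simulate_compendium(sim_config(n_genes = 5000), seed = 17)
  d <- sim$design
  em_cols <- d$sample_id[d$tissue == "embryo"]
  ref_cols <- d$sample_id[d$tissue %in% c("root", "leaf", "seedling", "ovary")]
  genes <- sim$truth$predominant$gene[sim$truth$predominant$class == "embryo"]
  expect_gt(length(genes), 200)
  diffs <- rowMeans(sim$matrix[genes, em_cols]) - rowMeans(sim$matrix[genes, ref_cols])
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 2), 3 * se)
})

test_that("replicate variances follow the configured scaled inverse-chi-square prior", {
  sim <- simulate_compendium(sim_config(n_genes = 4000), seed = 17)
  d <- sim$design
  # per-group replicate variances pool into a d_g = n_groups-of-freedom fit;
  # use the moment estimator through a null within-group contrast
  g1 <- d$sample_id[d$group == "root"]
  g2 <- d$sample_id[d$group == "leaf"]
  fit <- fit_contrast(sim$matrix, g1, g2)
  res <- moderate(fit)
  expect_gt(attr(res, "d0"), 4)
  expect_lt(attr(res, "d0"), 16)
  expect_lt(abs(attr(res, "s0sq") - 0.02) / 0.02, 0.3)
})

test_that("the cold simulator plants treated-only effects with the stated asymmetry", {
  cold <- simulate_cold_experiment(sim_config(n_genes = 2000), seed = 17)
  tr <- cold$truth$cold
  expect_identical(sum(tr$stage == 4 & tr$direction == "down"), 150L)
  expect_identical(sum(tr$stage == 4 & tr$direction == "up"), 50L)
  d <- cold$design
  # control samples carry no cold offset: a planted-down gene has equal
  # means across the two control groups
  g <- tr$gene[tr$stage == 4 & tr$direction == "down"][1:50]
  ctrl6 <- d$sample_id[d$group == "ZH_seed_6"]
  cold6 <- d$sample_id[d$group == "ZH_seed_6_cold"]
  delta <- rowMeans(cold$matrix[g, cold6, drop = FALSE]) -
    rowMeans(cold$matrix[g, ctrl6, drop = FALSE])
  expect_lt(mean(delta), -1.5)
})

test_that("co-expression modules realize the target correlation and stay separate", {
  cx <- simulate_coexpression_collection(n_arrays = 60, seed = 17)
  prof <- pcc_profiles(cx$matrix, cx$truth$modules$tf)
  mod <- cx$truth$modules
  med <- median(prof[mod$tf[1], mod$members[[1]]])
  expect_gt(med, 0.7)
  expect_lt(med, 0.9)

  # cross-module correlations centred at zero
  cross <- prof[mod$tf[1], mod$members[[2]]]
  expect_lt(abs(mean(cross)), 0.1)

  # loading 0 -> members are plain noise around zero
  cx0 <- simulate_coexpression_collection(n_arrays = 60, expected_pcc = 0,
                                          seed = 17)
  prof0 <- pcc_profiles(cx0$matrix, cx0$truth$modules$tf)
  mem0 <- prof0[cx0$truth$modules$tf[1], cx0$truth$modules$members[[1]]]
  expect_lt(abs(mean(mem0)), 0.1)

  expect_error(simulate_coexpression_collection(
    modules = coexpression_modules(1, 50), n_genes = 40), "smaller than n_genes")
})

test_that("promoter simulation plants motifs and reproduces bit-for-bit", {
  lib <- place_like_library()
  pp <- simulate_promoters(n_genes = 20, length = 300, motifs = lib,
                           group_size = 20, target_fraction_in_group = 1,
                           background_fraction = 0, seed = 17)
  hits <- scan_motifs(pp$promoters, lib[lib$motif_id == "ABRE", ])
  expect_true(all(hits$present))

  pp2 <- simulate_promoters(n_genes = 20, length = 300, motifs = lib,
                            group_size = 20, target_fraction_in_group = 1,
                            background_fraction = 0, seed = 17)
  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(pp$genome, fa1)
  write_genome_fasta(pp2$genome, fa2)
  expect_identical(readLines(fa1), readLines(fa2))

  expect_error(simulate_promoters(n_genes = 5, length = 6, motifs = lib,
                                  group_size = 5, seed = 1),
               "longer than promoter")
  expect_error(simulate_promoters(n_genes = 5, length = 300, motifs = lib,
                                  group_size = 5,
                                  target_fraction_in_group = 0.1,
                                  background_fraction = 0.5, seed = 1),
               "background_fraction")
})

test_that("background motif hits match the closed-form expectation", {
  # 8-mer on both strands of an L-nt i.i.d. promoter at GC 0.5:
  # E[hits] = 2 (L - 7) / 4^8
  lib <- motif_library(c(M8 = "TGTAAAGC"))
  pp <- simulate_promoters(n_genes = 500, length = 3000, motifs = lib,
                           group_size = 1, target_fraction_in_group = 0,
                           background_fraction = 0, gc = 0.5, seed = 17)
  hits <- scan_motifs(pp$promoters, lib)
  expected <- 2 * (3000 - 8 + 1) / 4^8
  expect_equal(expected, 0.0914, tolerance = 0.01)
  se <- sqrt(expected / 500)  # Poisson-like Monte-Carlo error
  expect_lt(abs(mean(hits$count) - expected), 4 * se)
})
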
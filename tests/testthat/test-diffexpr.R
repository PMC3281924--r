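test_that("fit_contrast computes the pooled two-group statistics", {
  m <- toy_matrix(matrix(c(4, 4, 2, 2,
                           1, 3, 2, 2), 2, 4, byrow = TRUE),
                  samples = c("a1", "a2", "b1", "b2"))
  fit <- fit_contrast(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(fit$estimate, c(2, 0))
  expect_equal(fit$s2, c(0, 1))
  expect_equal(fit$df, c(2, 2))
  expect_equal(attr(fit, "v"), 1)

  # shift invariance
  fit2 <- fit_contrast(m + 5, c("a1", "a2"), c("b1", "b2"))
  expect_equal(fit2$estimate, fit$estimate)

  expect_error(fit_contrast(m, c("a1", "a2"), c("a2", "b1")), "overlap")
  expect_error(fit_contrast(m, "a1", c("b1", "b2")), "at least 2")
})

test_that("moderation collapses to ordinary t in the homoscedastic limit", {
  # identical s2 for every gene: the estimated prior takes over (d0 -> Inf)
  # and, once the residual degrees of freedom are large enough that the
  # log-variance bias correction is negligible, the moderated t equals the
  # ordinary pooled t
  set.seed(17)
  n <- 200
  nrep <- 20
  m <- toy_matrix(matrix(rnorm(n * 2 * nrep), n, 2 * nrep))
  ga <- colnames(m)[1:nrep]
  gb <- colnames(m)[(nrep + 1):(2 * nrep)]
  base <- rowMeans(m)
  # rescale every gene's residuals to the same pooled variance c = 0.5
  fit0 <- fit_contrast(m, ga, gb)
  scale <- sqrt(0.5 / fit0$s2)
  m <- toy_matrix((m - base) * scale + base)
  fit <- fit_contrast(m, ga, gb)
  expect_true(all(abs(fit$s2 - 0.5) < 1e-10))
  res <- moderate(fit)
  expect_false(is.finite(attr(res, "d0")))
  expect_equal(attr(res, "s0sq"), 0.5, tolerance = 0.05)
  ordinary_t <- fit$estimate / sqrt(fit$s2 * attr(fit, "v"))
  expect_equal(res$t, ordinary_t, tolerance = 0.05)
})

test_that("moderation matches the established empirical-Bayes reference", {
  skip_if_not_installed("limma")
  set.seed(17)
  n <- 500
  m <- toy_matrix(matrix(rnorm(n * 6, sd = rep(sqrt(4 * 0.05 / rchisq(n, 4)), 6)),
                         n, 6),
                  samples = c("a1", "a2", "a3", "b1", "b2", "b3"))
  m[1:50, 1:3] <- m[1:50, 1:3] + 2
  res <- moderate(fit_contrast(m, c("a1", "a2", "a3"), c("b1", "b2", "b3")))
  eb <- limma::eBayes(limma::lmFit(m, cbind(1, rep(c(1, 0), each = 3))))
  expect_equal(attr(res, "d0"), eb$df.prior, tolerance = 1e-8)
  expect_equal(attr(res, "s0sq"), eb$s2.prior, tolerance = 1e-8)
  expect_equal(res$t, unname(eb$t[, 2]), tolerance = 1e-10)
  expect_equal(res$p, unname(eb$p.value[, 2]), tolerance = 1e-10)
})

test_that("all-zero variances fall back to a floor with a warning", {
  m <- toy_matrix(matrix(rep(c(2, 2, 1, 1), each = 60), 60, 4),
                  samples = c("a1", "a2", "b1", "b2"))
  fit <- fit_contrast(m, c("a1", "a2"), c("b1", "b2"))
  expect_warning(res <- moderate(fit), "floor")
  expect_true(all(is.finite(res$t)))
})

test_that("bh_fdr implements the step-up definition", {
  expect_equal(bh_fdr(0.005), 0.005)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("predominance calls follow the q and fold thresholds", {
  mk <- function(genes, q, est) {
    out <- tibble::tibble(gene = genes, estimate = est, s2 = 1, df = 2,
                          s2_post = 1, t = 1, p = q, q = q)
    class(out) <- c("moderated_contrast", class(out))
    out
  }
  genes <- c("g1", "g2", "g3", "g4")
  em <- mk(genes, q = c(1e-6, 1e-6, 1e-3, 0.5), est = c(2, 2, 3, 0))
  en <- mk(genes, q = c(0.5, 1e-6, 1e-3, 0.5), est = c(0, 2, 3, 0))
  cls <- call_predominant(em, en)
  expect_identical(cls$class, c("embryo", "both", "none", "none"))
  # q = 0.001 with huge fold still fails the FDR-adjusted p < 0.0005 gate
  expect_identical(cls$class[cls$gene == "g3"], "none")
  expect_error(call_predominant(em, mk(c("g1", "g2", "g3", "gX"), rep(1, 4), rep(0, 4))),
               "universe")
})

test_that("the time-course F agrees with the reference ANOVA on random toys", {
  set.seed(17)
  for (i in 1:50) {
    m <- toy_matrix(matrix(rnorm(8, sd = runif(1, 0.1, 2)), 1, 8),
                    samples = sprintf("s%d", 1:8))
    design <- toy_design(colnames(m), "embryo",
                         stage = rep(c(3L, 6L, 9L, 12L), each = 2),
                         replicate = rep(1:2, 4))
    tc <- anova_timecourse(m, design, "embryo")
    ref <- anova(lm(m[1, ] ~ factor(rep(1:4, each = 2))))
    expect_equal(tc$f, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(tc$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("degenerate and planted time courses behave as specified", {
  m <- toy_matrix(matrix(5, 2, 8), samples = sprintf("s%d", 1:8))
  design <- toy_design(colnames(m), "embryo",
                       stage = rep(c(3L, 6L, 9L, 12L), each = 2),
                       replicate = rep(1:2, 4))
  tc <- anova_timecourse(m, design, "embryo")
  expect_equal(tc$f, c(0, 0))
  expect_equal(tc$p, c(1, 1))

  set.seed(17)
  up <- rep(c(0, 4 / 3, 8 / 3, 4), each = 2) + rnorm(8, sd = 0.15)
  m2 <- toy_matrix(matrix(up, 1, 8), samples = colnames(m))
  tc2 <- anova_timecourse(m2, design, "embryo")
  expect_lt(tc2$p, 1e-3)
  expect_identical(tc2$direction, "up")

  expect_error(anova_timecourse(m, toy_design(colnames(m), "embryo",
                                              stage = rep(c(3L, 6L), each = 4),
                                              replicate = rep(1:4, 2)), "embryo"),
               "3 stages")
})

test_that("cold regulation is sign-symmetric and sensitive to planted effects", {
  cold <- simulate_cold_experiment(sim_config(n_genes = 2000), seed = 17)
  pairs <- cold$truth$pairs["ZH_4DAF"]
  reg <- call_cold_regulated(cold$matrix, cold$design, pairs)
  truth4 <- cold$truth$cold[cold$truth$cold$stage == 4, ]
  hit <- merge(truth4, reg, by = "gene")
  expect_gte(nrow(hit) / nrow(truth4), 0.9)
  expect_true(all(hit$direction.x == hit$direction.y))

  swapped <- list(ZH_4DAF = c(treated = "ZH_seed_6", control = "ZH_seed_6_cold"))
  reg_sw <- call_cold_regulated(cold$matrix, cold$design, swapped)
  expect_setequal(reg$gene[reg$direction == "up"],
                  reg_sw$gene[reg_sw$direction == "down"])
  expect_setequal(reg$gene[reg$direction == "down"],
                  reg_sw$gene[reg_sw$direction == "up"])
})

test_that("null cold comparisons stay within chance bounds", {
  set.seed(17)
  n <- 4000
  m <- toy_matrix(matrix(rnorm(n * 4, sd = rep(sqrt(8 * 0.02 / rchisq(n, 8)), 4)),
                         n, 4) + 8,
                  samples = c("c1", "c2", "t1", "t2"))
  design <- toy_design(colnames(m), "seed", stage = 6L, replicate = c(1:2, 1:2),
                       treatment = rep(c("control", "cold"), each = 2))
  reg <- call_cold_regulated(m, design,
                             list(P = c(treated = "seed_6_cold", control = "seed_6")))
  # p < 0.05 AND |log2FC| > 1: the fold filter makes calls much rarer than
  # 5%; allow a generous binomial envelope around the observed joint rate
  expect_lt(nrow(reg) / n, 0.02)
})

test_that("trend concordance counts shared directions", {
  a <- tibble::tibble(gene = c("g1", "g2", "g3"), direction = c("up", "down", "up"))
  b <- tibble::tibble(gene = c("g2", "g3", "g4"), direction = c("down", "down", "up"))
  tc <- trend_concordance(a, b)
  expect_identical(tc$n_common, 2L)
  expect_equal(tc$fraction_same, 0.5)
  expect_equal(trend_concordance(a, a)$fraction_same, 1)
  none <- trend_concordance(a, tibble::tibble(gene = "gX", direction = "up"))
  expect_identical(none$n_common, 0L)
  expect_true(is.na(none$fraction_same))
})

test_that("independently replicated experiments agree on trends", {
  # two noisy realizations of the same planted truth, compared like two
  # cultivars profiled on different platforms
  cfg <- sim_config(n_genes = 3000)
  simA <- simulate_compendium(cfg, seed = 17)
  # second platform profiling the same biology: same planted truth, an
  # independent measurement-noise layer
  set.seed(18)
  mB <- simA$matrix + matrix(rnorm(length(simA$matrix), sd = 0.2),
                             nrow(simA$matrix))
  dimnames(mB) <- dimnames(simA$matrix)
  dirs <- function(m) {
    tc <- anova_timecourse(m, simA$design, "embryo")
    reg <- tc[tc$p < 1e-3, ]
    tibble::tibble(gene = reg$gene, direction = reg$direction)
  }
  conc <- trend_concordance(dirs(simA$matrix), dirs(mB))
  expect_gt(conc$n_common, 20)
  expect_gte(conc$fraction_same, 0.8)
})
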
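#' Simulation configuration for the developing-seed compendium
#'
#' Defaults mirror the study design this package targets: embryo sampled at
#' 3, 6, 9 and 12 days after fertilization (DAF), endosperm at 3, 6, 9 and
#' 16 DAF, plus root, leaf, seedling and ovary as reference tissues, two
#' biological replicates per sample. Planted-class fractions approximate the
#' observed prevalence of predominant and regulated genes; the absent
#' fraction (0.30) mirrors the roughly one third of gene models never
#' detected on the array and is calibrated to the default per-array 30%
#' quantile detection rule.
#'
#' Effect sizes are on the log2 scale: tissue-predominant genes are shifted
#' by `effect_predominant` (default +2, i.e. 4-fold) in their tissue;
#' time-course genes traverse `effect_timecourse` log2 units (default 4,
#' i.e. 16-fold first-to-last stage) through stage offsets centred on zero,
#' so regulated genes are not incidentally tissue-predominant. Gene-wise
#' noise variances are drawn from a scaled inverse-chi-square prior with
#' `d0` prior degrees of freedom and prior value `s0sq` (log2^2 units);
#' the defaults (8, 0.02) give replicate standard deviations around 0.14,
#' consistent with high replicate correlations on good arrays.
#'
#' @param n_genes Number of gene models.
#' @param frac_embryo,frac_endosperm,frac_both Fractions of genes planted as
#'   predominantly expressed in embryo, endosperm, or both.
#' @param frac_timecourse_embryo,frac_timecourse_endosperm Fractions planted
#'   as regulated in time within each seed tissue (half up, half down).
#' @param frac_absent Fraction of genes expressed nowhere.
#' @param effect_predominant,effect_timecourse,effect_cold Planted log2
#'   effect sizes (see Details).
#' @param baseline_mean,baseline_sd,baseline_min Truncated-normal baseline
#'   log2 intensity of expressed genes.
#' @param absent_mean,absent_sd Background log2 intensity of absent genes.
#' @param d0,s0sq Scaled inverse-chi-square variance prior.
#' @param n_replicates Biological replicates per sample group.
#' @param cold_down_4,cold_up_4,cold_down_10,cold_up_10 Planted cold-response
#'   counts per treatment stage (more down- than up-regulation at the early
#'   stage by default, the asymmetry characteristic of chilled early seed).
#' @param hf_attenuation Multiplier applied to cold effects in the
#'   cold-tolerant cultivar.
#' @param heavy_tail If `TRUE`, 5% of noise values are inflated threefold
#'   (contamination switch for robustness checks).
#' @param seed Integer seed; every simulator draws all randomness from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       frac_embryo = 0.045,
                       frac_endosperm = 0.035,
                       frac_both = 0.012,
                       frac_timecourse_embryo = 0.03,
                       frac_timecourse_endosperm = 0.03,
                       frac_absent = 0.30,
                       effect_predominant = 2,
                       effect_timecourse = 4,
                       effect_cold = 2,
                       baseline_mean = 8.5,
                       baseline_sd = 1,
                       baseline_min = 6.5,
                       absent_mean = 4,
                       absent_sd = 0.5,
                       d0 = 8,
                       s0sq = 0.02,
                       n_replicates = 2,
                       cold_down_4 = 150,
                       cold_up_4 = 50,
                       cold_down_10 = 75,
                       cold_up_10 = 75,
                       hf_attenuation = 0.5,
                       heavy_tail = FALSE,
                       seed = 17) {
  cfg <- as.list(environment())
  fr <- cfg[startsWith(names(cfg), "frac_")]
  if (sum(unlist(fr)) > 1) {
    stop("planted-class fractions sum to more than 1", call. = FALSE)
  }
  if (any(unlist(fr) < 0)) stop("fractions must be non-negative", call. = FALSE)
  if (cfg$effect_predominant <= 0 || cfg$effect_timecourse <= 0 || cfg$effect_cold <= 0) {
    stop("effect sizes must be positive", call. = FALSE)
  }
  if (cfg$d0 <= 0 || cfg$s0sq <= 0) stop("variance prior must be positive", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Sample layout of the development compendium.
development_design <- function(n_replicates = 2) {
  groups <- dplyr::bind_rows(
    tibble::tibble(tissue = "embryo", stage = c(3L, 6L, 9L, 12L)),
    tibble::tibble(tissue = "endosperm", stage = c(3L, 6L, 9L, 16L)),
    tibble::tibble(tissue = c("root", "leaf", "seedling", "ovary"), stage = NA_integer_)
  )
  d <- tidyr::expand_grid(groups, replicate = seq_len(n_replicates))
  d$treatment <- "control"
  d$sample_id <- paste0(d$tissue, ifelse(is.na(d$stage), "", paste0("_", d$stage)),
                        "_r", d$replicate)
  validate_sample_design(d)
}

# Draw gene-wise variances from the scaled inverse-chi-square prior.
draw_sigma2 <- function(n, d0, s0sq) d0 * s0sq / stats::rchisq(n, df = d0)

# Truncated-normal baselines for expressed genes.
draw_baseline <- function(n, mean, sd, lower) {
  stats::qnorm(stats::runif(n, stats::pnorm(lower, mean, sd), 1), mean, sd)
}

gene_noise <- function(n_genes, n_samples, sigma2, heavy_tail = FALSE) {
  eps <- stats::rnorm(n_genes * n_samples, sd = rep(sqrt(sigma2), n_samples))
  if (heavy_tail) {
    hit <- stats::runif(length(eps)) < 0.05
    eps[hit] <- eps[hit] * 3
  }
  matrix(eps, nrow = n_genes, ncol = n_samples)
}

#' Simulate a developing-seed expression compendium with planted truth
#'
#' Gene values are `baseline + planted offsets + noise` on the log2 scale,
#' with gene-wise noise variances from a scaled inverse-chi-square prior.
#' Absent genes are drawn from a background distribution below the detection
#' threshold. Fully reproducible from the seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return A list with `matrix` (genes x samples log2 values), `design`
#'   (sample tibble) and `truth` (planted classes, variance prior, seed).
#' @export
simulate_compendium <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n <- cfg$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  design <- development_design(cfg$n_replicates)
  ns <- nrow(design)

  counts <- c(
    embryo = round(cfg$frac_embryo * n),
    endosperm = round(cfg$frac_endosperm * n),
    both = round(cfg$frac_both * n),
    tc_embryo = round(cfg$frac_timecourse_embryo * n),
    tc_endosperm = round(cfg$frac_timecourse_endosperm * n),
    absent = round(cfg$frac_absent * n)
  )
  shuffled <- sample(genes)
  ends <- cumsum(counts)
  starts <- ends - counts + 1
  slices <- stats::setNames(
    lapply(seq_along(counts), function(i) {
      if (counts[i] == 0) character(0) else shuffled[starts[i]:ends[i]]
    }),
    names(counts)
  )
  absent <- slices$absent

  baseline <- numeric(n)
  names(baseline) <- genes
  present <- setdiff(genes, absent)
  baseline[present] <- draw_baseline(length(present), cfg$baseline_mean,
                                     cfg$baseline_sd, cfg$baseline_min)
  baseline[absent] <- stats::rnorm(length(absent), cfg$absent_mean, cfg$absent_sd)

  sigma2 <- stats::setNames(draw_sigma2(n, cfg$d0, cfg$s0sq), genes)

  offsets <- matrix(0, n, ns, dimnames = list(genes, design$sample_id))
  embryo_cols <- design$tissue == "embryo"
  endosperm_cols <- design$tissue == "endosperm"
  offsets[slices$embryo, embryo_cols] <- offsets[slices$embryo, embryo_cols] + cfg$effect_predominant
  offsets[slices$endosperm, endosperm_cols] <- offsets[slices$endosperm, endosperm_cols] + cfg$effect_predominant
  offsets[slices$both, embryo_cols | endosperm_cols] <-
    offsets[slices$both, embryo_cols | endosperm_cols] + cfg$effect_predominant

  tc <- list(embryo = slices$tc_embryo, endosperm = slices$tc_endosperm)
  timecourse <- tibble::tibble(gene = character(0), tissue = character(0),
                               direction = character(0), swing = numeric(0))
  for (tis in names(tc)) {
    tg <- tc[[tis]]
    if (!length(tg)) next
    stages <- sort(unique(design$stage[design$tissue == tis]))
    offs <- seq(-cfg$effect_timecourse / 2, cfg$effect_timecourse / 2,
                length.out = length(stages))
    dir <- rep(c("up", "down"), length.out = length(tg))
    for (i in seq_along(tg)) {
      stage_offs <- if (dir[i] == "up") offs else rev(offs)
      for (j in seq_along(stages)) {
        cols <- design$tissue == tis & design$stage == stages[j] & !is.na(design$stage)
        offsets[tg[i], cols] <- offsets[tg[i], cols] + stage_offs[j]
      }
    }
    timecourse <- dplyr::bind_rows(timecourse, tibble::tibble(
      gene = tg, tissue = tis, direction = dir, swing = cfg$effect_timecourse))
  }

  values <- baseline + offsets + gene_noise(n, ns, sigma2, cfg$heavy_tail)
  dimnames(values) <- list(genes, design$sample_id)

  predominant <- dplyr::bind_rows(
    tibble::tibble(gene = slices$embryo, class = "embryo"),
    tibble::tibble(gene = slices$endosperm, class = "endosperm"),
    tibble::tibble(gene = slices$both, class = "both")
  )
  predominant$effect <- cfg$effect_predominant

  truth <- structure(list(
    predominant = predominant,
    timecourse = timecourse,
    absent = absent,
    expressed = present,
    variance_prior = list(d0 = cfg$d0, s0sq = cfg$s0sq),
    sigma2 = sigma2,
    baseline = baseline,
    seed = seed
  ), class = "synthetic_truth")

  list(matrix = expression_matrix(values), design = design, truth = truth)
}

#' Simulate the paired cold-treatment experiment
#'
#' Two cultivars (a cold-sensitive and a cold-tolerant one), each with seed
#' treated at 4 or 10 DAF for two days at low temperature and harvested
#' alongside untreated controls of the same chronological age: eight sample
#' groups, two replicates each. Cold effects are additive on the log2 scale
#' and applied only to the treated samples of the planted stage; effects in
#' the tolerant cultivar are attenuated by `cfg$hf_attenuation`.
#'
#' @inheritParams simulate_compendium
#' @return A list with `matrix`, `design`, `truth` (cold truth tibble,
#'   comparison pairs, variance prior) .
#' @export
simulate_cold_experiment <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed + 1L)
  n <- cfg$n_genes
  genes <- sprintf("g%05d", seq_len(n))

  layout <- tidyr::expand_grid(
    cultivar = c("ZH", "HF"),
    tibble::tibble(stage = c(6L, 6L, 12L, 12L),
                   treatment = c("cold", "control", "cold", "control"),
                   treated_at = c(4L, NA, 10L, NA))
  )
  design <- tidyr::expand_grid(layout, replicate = seq_len(cfg$n_replicates))
  design$tissue <- "seed"
  design$sample_id <- paste0(design$cultivar, "_", design$stage,
                             ifelse(design$treatment == "cold", "C", ""),
                             "_r", design$replicate)
  design <- validate_sample_design(design)
  ns <- nrow(design)

  n_absent <- round(cfg$frac_absent * n)
  shuffled <- sample(genes)
  absent <- shuffled[seq_len(n_absent)]
  pool <- shuffled[-seq_len(n_absent)]
  picks <- c(cfg$cold_down_4, cfg$cold_up_4, cfg$cold_down_10, cfg$cold_up_10)
  if (sum(picks) > length(pool)) stop("too many planted cold genes", call. = FALSE)
  cold <- tibble::tibble(
    gene = pool[seq_len(sum(picks))],
    stage = rep(c(4L, 4L, 10L, 10L), picks),
    direction = rep(c("down", "up", "down", "up"), picks),
    effect = cfg$effect_cold
  )

  baseline <- stats::setNames(numeric(n), genes)
  present <- setdiff(genes, absent)
  baseline[present] <- draw_baseline(length(present), cfg$baseline_mean,
                                     cfg$baseline_sd, cfg$baseline_min)
  baseline[absent] <- stats::rnorm(length(absent), cfg$absent_mean, cfg$absent_sd)
  sigma2 <- stats::setNames(draw_sigma2(n, cfg$d0, cfg$s0sq), genes)

  offsets <- matrix(0, n, ns, dimnames = list(genes, design$sample_id))
  for (i in seq_len(nrow(cold))) {
    cols <- design$treatment == "cold" &
      !is.na(design$treated_at) & design$treated_at == cold$stage[i]
    eff <- ifelse(cold$direction[i] == "up", 1, -1) * cold$effect[i]
    scale <- ifelse(design$cultivar[cols] == "HF", cfg$hf_attenuation, 1)
    offsets[cold$gene[i], cols] <- eff * scale
  }

  values <- baseline + offsets + gene_noise(n, ns, sigma2, cfg$heavy_tail)
  dimnames(values) <- list(genes, design$sample_id)

  pairs <- list(
    ZH_4DAF = c(treated = "ZH_seed_6_cold", control = "ZH_seed_6"),
    ZH_10DAF = c(treated = "ZH_seed_12_cold", control = "ZH_seed_12"),
    HF_4DAF = c(treated = "HF_seed_6_cold", control = "HF_seed_6"),
    HF_10DAF = c(treated = "HF_seed_12_cold", control = "HF_seed_12")
  )

  truth <- structure(list(
    cold = cold,
    pairs = pairs,
    absent = absent,
    expressed = present,
    variance_prior = list(d0 = cfg$d0, s0sq = cfg$s0sq),
    sigma2 = sigma2,
    seed = seed
  ), class = "synthetic_truth")

  list(matrix = expression_matrix(values), design = design, truth = truth)
}

#' Default module specification for the co-expression simulator
#' @param n_modules Number of TF-centred modules.
#' @param n_members Member genes per module.
#' @return Tibble with columns `tf`, `n_members`, `term`, `label`.
#' @export
coexpression_modules <- function(n_modules = 5, n_members = 50) {
  tibble::tibble(
    tf = sprintf("TF%02d", seq_len(n_modules)),
    n_members = n_members,
    term = sprintf("GO:MOD%02d", seq_len(n_modules)),
    label = sprintf("planted module %02d", seq_len(n_modules))
  )
}

#' Simulate a many-array co-expression collection with planted TF modules
#'
#' Each module's TF gets a standard-normal profile across arrays; members
#' follow `loading * TF + noise` with loading and noise variance set so the
#' expected Pearson correlation with the TF equals `expected_pcc`.
#' Non-members are independent noise. Values are shifted to a log2-like
#' scale (mean 8) which leaves correlations untouched.
#'
#' @param n_arrays Number of arrays in the compendium.
#' @param modules Module table, see [coexpression_modules()].
#' @param n_genes Total genes (TFs + members + unrelated background).
#' @param expected_pcc Target TF-member correlation (default 0.8).
#' @param seed Integer seed.
#' @return List with `matrix` and `truth` (`modules` tibble with a `members`
#'   list-column).
#' @export
simulate_coexpression_collection <- function(n_arrays = 60,
                                             modules = coexpression_modules(),
                                             n_genes = 2000,
                                             expected_pcc = 0.8,
                                             seed = 17) {
  modules <- tibble::as_tibble(modules)
  if (any(modules$n_members >= n_genes)) {
    stop("module member count must be smaller than n_genes", call. = FALSE)
  }
  n_needed <- nrow(modules) + sum(modules$n_members)
  if (n_needed > n_genes) stop("modules need more genes than n_genes", call. = FALSE)
  if (abs(expected_pcc) > 1) stop("expected_pcc must be in [-1, 1]", call. = FALSE)
  set.seed(seed)

  pool <- sprintf("c%05d", seq_len(n_genes - nrow(modules)))
  arrays <- sprintf("array%03d", seq_len(n_arrays))
  values <- matrix(stats::rnorm((n_genes) * n_arrays), ncol = n_arrays)
  rownames(values) <- c(modules$tf, pool)
  colnames(values) <- arrays

  # Module seed profiles represent distinct regulatory programs: centred and
  # orthogonalized so planted modules are mutually uncorrelated by
  # construction (chance TF-TF correlation would otherwise leak each
  # module's members into other TFs' neighborhoods).
  if (nrow(modules) > 1) {
    z <- matrix(stats::rnorm(n_arrays * nrow(modules)), ncol = nrow(modules))
    z <- sweep(z, 2, colMeans(z))
    q <- qr.Q(qr(z)) * sqrt(n_arrays - 1)
    values[modules$tf, ] <- t(q)
  }

  rho <- expected_pcc
  members <- vector("list", nrow(modules))
  next_gene <- 1L
  for (i in seq_len(nrow(modules))) {
    tf_profile <- values[modules$tf[i], ]
    mem <- pool[next_gene:(next_gene + modules$n_members[i] - 1L)]
    next_gene <- next_gene + modules$n_members[i]
    eps <- matrix(stats::rnorm(length(mem) * n_arrays), ncol = n_arrays)
    values[mem, ] <- rho * matrix(tf_profile, length(mem), n_arrays, byrow = TRUE) +
      sqrt(1 - rho^2) * eps
    members[[i]] <- mem
  }
  modules$members <- members
  values <- values + 8

  truth <- structure(list(
    modules = modules,
    background = rownames(values),
    expected_pcc = expected_pcc,
    seed = seed
  ), class = "synthetic_truth")

  list(matrix = expression_matrix(values), truth = truth)
}

#' Simulate promoters, a genome and gene models with planted motif instances
#'
#' Generates i.i.d. background promoters at the stated GC content, plants one
#' exact instance of the chosen motif (uniform random position and strand)
#' into a `target_fraction_in_group` share of the first `group_size` genes
#' and a `background_fraction` share of the remaining genes, and assembles a
#' one-contig-per-gene genome plus GFF3-style gene models consistent with
#' [extract_upstream()] conventions (half the genes are placed on the minus
#' strand).
#'
#' @param n_genes Number of genes/promoters.
#' @param length Promoter length in nt.
#' @param motifs A [motif_library()].
#' @param group_size Size of the designated gene group (the first genes).
#' @param target_fraction_in_group Fraction of group genes receiving a
#'   planted instance.
#' @param background_fraction Fraction of non-group genes receiving one.
#' @param gc Background GC content.
#' @param planted_motif Motif id to plant (default: first in the library).
#' @param gene_length Length of the downstream gene body.
#' @param seed Integer seed.
#' @return List with `genome` (named character, one contig per gene),
#'   `models` (GFF3 fields tibble), `promoters` (named character, 5'->3' on
#'   the gene's sense strand) and `truth` (planted targets, group, motif).
#' @export
simulate_promoters <- function(n_genes = 1000,
                               length = 1000,
                               motifs,
                               group_size = 100,
                               target_fraction_in_group = 0.4,
                               background_fraction = 0.05,
                               gc = 0.5,
                               planted_motif = NULL,
                               gene_length = 90,
                               seed = 17) {
  motifs <- motif_library(motifs)
  if (is.null(planted_motif)) planted_motif <- motifs$motif_id[1]
  pattern <- motifs$pattern[match(planted_motif, motifs$motif_id)]
  if (is.na(pattern)) stop("planted motif not in library", call. = FALSE)
  if (nchar(pattern) > length) stop("motif longer than promoter", call. = FALSE)
  if (background_fraction < 0 || background_fraction > target_fraction_in_group ||
      target_fraction_in_group > 1) {
    stop("need 0 <= background_fraction <= target_fraction_in_group <= 1", call. = FALSE)
  }
  if (group_size > n_genes) stop("group_size exceeds n_genes", call. = FALSE)
  set.seed(seed)

  genes <- sprintf("g%04d", seq_len(n_genes))
  bases <- c("A", "C", "G", "T")
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chars <- sample(bases, n_genes * length, replace = TRUE, prob = base_p)
  promoters <- apply(matrix(chars, nrow = length), 2, paste, collapse = "")
  names(promoters) <- genes

  group <- genes[seq_len(group_size)]
  rest <- setdiff(genes, group)
  targets <- c(
    sample(group, round(target_fraction_in_group * length(group))),
    if (length(rest)) sample(rest, round(background_fraction * length(rest)))
  )
  w <- nchar(pattern)
  for (g in targets) {
    ins <- instantiate_iupac(pattern)
    if (stats::runif(1) < 0.5) ins <- revcomp(ins)
    pos <- sample.int(length - w + 1L, 1)
    substr(promoters[g], pos, pos + w - 1L) <- ins
  }

  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  bodies <- apply(matrix(sample(bases, n_genes * (gene_length - 3L), replace = TRUE),
                         nrow = gene_length - 3L), 2, paste, collapse = "")
  bodies <- paste0("ATG", bodies)

  contigs <- ifelse(strand == "+",
                    paste0(promoters, bodies),
                    paste0(revcomp(bodies), revcomp(promoters)))
  names(contigs) <- paste0("ctg_", genes)

  models <- tibble::tibble(
    seqid = names(contigs),
    source = "riceseedtx_sim",
    type = "gene",
    start = ifelse(strand == "+", length + 1L, 1L),
    end = ifelse(strand == "+", length + gene_length, gene_length),
    score = ".",
    strand = strand,
    phase = ".",
    attributes = paste0("ID=", genes)
  )

  truth <- structure(list(
    motif_targets = tibble::tibble(motif = planted_motif, gene = targets),
    group = group,
    planted_motif = planted_motif,
    pattern = pattern,
    seed = seed
  ), class = "synthetic_truth")

  list(genome = contigs, models = models, promoters = promoters, truth = truth)
}

#' Write a genome as FASTA
#' @param genome Named character vector of contig sequences.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write gene models as GFF3
#' @param models Tibble with the nine GFF3 columns (as from
#'   [simulate_promoters()]).
#' @param path Output file.
#' @export
write_gff3 <- function(models, path) {
  cols <- c("seqid", "source", "type", "start", "end", "score", "strand",
            "phase", "attributes")
  stopifnot(all(cols %in% names(models)))
  lines <- do.call(paste, c(unname(as.list(models[cols])), sep = "\t"))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
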
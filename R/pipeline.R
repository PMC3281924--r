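#' Configuration for a pipeline run
#'
#' Inputs may be in-memory objects (matrix/design tibbles from the
#' simulators or readers) or file paths (TSV matrix/design, GMT gene sets);
#' referenced paths must exist at validation time.
#'
#' @param matrix Expression matrix or TSV path.
#' @param design Sample design tibble or TSV path.
#' @param gene_sets Optional [category_map()] or GMT path.
#' @param thresholds See [default_thresholds()].
#' @param detection Detection rule, see [detection_call()].
#' @param normalize Quantile-normalize before analysis? Default `TRUE`.
#' @param background `"matrix"` (all genes after filtering, default) or
#'   `"genome"` (all genes in the matrix before filtering) for enrichment.
#' @param pairs Treated/control group pairs for the cold pipeline.
#' @param out_dir Output directory for TSVs and the manifest.
#' @param seed Seed recorded in the run manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix, design, gene_sets = NULL,
                            thresholds = default_thresholds(),
                            detection = list(mode = "quantile", q = 0.30),
                            normalize = TRUE,
                            background = c("matrix", "genome"),
                            pairs = NULL,
                            out_dir = tempfile("riceseedtx_run_"),
                            seed = 17) {
  background <- match.arg(background)
  for (p in list(matrix, design, gene_sets)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(matrix = matrix, design = design, gene_sets = gene_sets,
                 thresholds = thresholds, detection = detection,
                 normalize = normalize, background = background, pairs = pairs,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(cfg) {
  m <- if (is.character(cfg$matrix)) read_expression_matrix(cfg$matrix) else expression_matrix(cfg$matrix)
  d <- if (is.character(cfg$design)) read_sample_design(cfg$design) else validate_sample_design(cfg$design)
  list(matrix = m, design = align_design(m, d))
}

# Stable fingerprint of the configuration for the run manifest.
config_hash <- function(cfg) {
  slim <- cfg[c("thresholds", "detection", "normalize", "background", "seed")]
  rlang::hash(slim)
}

write_stage_tsv <- function(x, out_dir, name) {
  readr::write_tsv(tibble::as_tibble(x), file.path(out_dir, paste0(name, ".tsv")))
}

#' Run the development (predominance + time-course) analysis
#'
#' Orchestrates preprocessing (optional quantile normalization, detection
#' calls, all-absent filtering, replicate QC), moderated contrasts of
#' embryo and endosperm against the vegetative reference tissues (root,
#' leaf, seedling, ovary) with predominance calls at the configured
#' thresholds, one-way stage ANOVA per seed tissue, and (when gene sets
#' are supplied) chi-square enrichment of each predominance class plus the
#' terms x sets `-log10 p` matrix. Per-stage TSVs and a JSON run manifest
#' (config hash, seed, class counts) land in `cfg$out_dir`; on error the
#' files created by this run are removed.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_development_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- character(0)
  on_error <- function(e) {
    unlink(created)
    stop("development pipeline failed at stage [", attr(e, "stage") %||% "unknown",
         "]: ", conditionMessage(e), call. = FALSE)
  }
  stage <- "load"
  tryCatch({
    inputs <- load_pipeline_inputs(cfg)
    m <- inputs$matrix
    design <- inputs$design

    stage <- "preprocess"
    if (isTRUE(cfg$normalize)) m <- quantile_normalize(m)
    calls <- detection_call(m, cfg$detection)
    qc <- replicate_qc(m, design)
    expressed_any <- expressed_genes(calls, design)
    seed_groups <- design$group[design$tissue %in% c("embryo", "endosperm")]
    expressed_seed <- expressed_genes(calls, design, scope = unique(seed_groups))
    filtered <- filter_low_expression(m, calls, mode = "all_absent")

    stage <- "diffexpr"
    th <- cfg$thresholds
    ref <- design$sample_id[design$tissue %in% c("root", "leaf", "seedling", "ovary")]
    embryo <- design$sample_id[design$tissue == "embryo"]
    endosperm <- design$sample_id[design$tissue == "endosperm"]
    fit_em <- moderate(fit_contrast(filtered, embryo, ref))
    fit_en <- moderate(fit_contrast(filtered, endosperm, ref))
    classes <- call_predominant(fit_em, fit_en, th)
    tc_em <- anova_timecourse(filtered, design, "embryo")
    tc_en <- anova_timecourse(filtered, design, "endosperm")

    stage <- "enrichment"
    enr <- NULL
    enr_matrix <- NULL
    if (!is.null(cfg$gene_sets)) {
      bg <- if (cfg$background == "matrix") rownames(filtered) else rownames(inputs$matrix)
      cats <- if (is.character(cfg$gene_sets)) read_gene_sets(cfg$gene_sets, bg) else cfg$gene_sets
      sets <- list(
        Em = classes$gene[classes$class == "embryo"],
        En = classes$gene[classes$class == "endosperm"],
        Both = classes$gene[classes$class == "both"],
        Em_T = tc_em$gene[tc_em$p < th$timecourse_p],
        En_T = tc_en$gene[tc_en$p < th$timecourse_p]
      )
      sets <- lapply(sets, intersect, y = cats$background)
      sets <- sets[lengths(sets) > 0]
      if (length(sets)) {
        enr <- lapply(sets, chisq_enrichment, cats = cats)
        enr_matrix <- suppressWarnings(enrichment_matrix(enr))
      }
    }

    stage <- "write"
    write_stage_tsv(qc, cfg$out_dir, "replicate_qc")
    write_stage_tsv(tibble::tibble(gene = expressed_any, scope = "any"),
                    cfg$out_dir, "expressed_any")
    write_stage_tsv(tibble::tibble(gene = expressed_seed, scope = "seed"),
                    cfg$out_dir, "expressed_seed")
    write_stage_tsv(fit_em, cfg$out_dir, "contrast_embryo")
    write_stage_tsv(fit_en, cfg$out_dir, "contrast_endosperm")
    write_stage_tsv(classes, cfg$out_dir, "predominance")
    write_stage_tsv(tc_em, cfg$out_dir, "timecourse_embryo")
    write_stage_tsv(tc_en, cfg$out_dir, "timecourse_endosperm")
    if (!is.null(enr_matrix)) {
      write_enrichment_matrix(enr_matrix, file.path(cfg$out_dir, "enrichment_matrix.tsv"))
    }
    created <- list.files(cfg$out_dir, full.names = TRUE)

    counts <- table(factor(classes$class, levels = c("embryo", "endosperm", "both", "none")))
    manifest <- list(
      config_hash = config_hash(cfg),
      seed = cfg$seed,
      n_genes = nrow(inputs$matrix),
      n_genes_filtered = nrow(filtered),
      n_expressed_any = length(expressed_any),
      n_expressed_seed = length(expressed_seed),
      pct_expressed_seed = expressed_percentage(length(expressed_seed),
                                                max(length(expressed_any), 1L)),
      class_counts = as.list(counts),
      d0 = list(embryo = attr(fit_em, "d0"), endosperm = attr(fit_en, "d0")),
      s0sq = list(embryo = attr(fit_em, "s0sq"), endosperm = attr(fit_en, "s0sq"))
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(matrix = filtered, design = design, calls = calls, qc = qc,
                   expressed_any = expressed_any, expressed_seed = expressed_seed,
                   contrast_embryo = fit_em, contrast_endosperm = fit_en,
                   predominance = classes, timecourse_embryo = tc_em,
                   timecourse_endosperm = tc_en, enrichment = enr,
                   enrichment_matrix = enr_matrix, manifest = manifest))
  }, error = function(e) { attr(e, "stage") <- stage; on_error(e) })
}

#' Run the cold-response analysis
#'
#' Per treated/control pair: moderated contrast, up/down sets at the cold
#' thresholds, and per-pair counts; optional trend-concordance reports
#' between named pairs of regulated sets (the common-gene comparison).
#' Writes TSVs and a JSON manifest to `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()] with `pairs` set.
#' @param compare Optional list of two-element character vectors naming
#'   pairs whose up/down maps should be compared for trend concordance.
#' @return Invisibly, a list with the regulated tibble, counts, optional
#'   concordance tables and the manifest.
#' @export
run_cold_analysis <- function(cfg, compare = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$pairs)) stop("cold pipeline needs cfg$pairs", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load"
  created <- character(0)
  tryCatch({
    inputs <- load_pipeline_inputs(cfg)
    m <- inputs$matrix
    if (isTRUE(cfg$normalize)) m <- quantile_normalize(m)
    calls <- detection_call(m, cfg$detection)
    filtered <- filter_low_expression(m, calls, mode = "all_absent")

    stage <- "diffexpr"
    regulated <- call_cold_regulated(filtered, inputs$design, cfg$pairs, cfg$thresholds)
    counts <- attr(regulated, "counts")

    stage <- "concordance"
    concordance <- NULL
    if (!is.null(compare)) {
      concordance <- lapply(compare, function(two) {
        a <- regulated[regulated$pair == two[1], c("gene", "direction")]
        b <- regulated[regulated$pair == two[2], c("gene", "direction")]
        tc <- trend_concordance(a, b)
        tibble::tibble(pair_a = two[1], pair_b = two[2],
                       n_common = tc$n_common, fraction_same = tc$fraction_same)
      })
      concordance <- dplyr::bind_rows(concordance)
    }

    stage <- "write"
    write_stage_tsv(regulated, cfg$out_dir, "cold_regulated")
    write_stage_tsv(counts, cfg$out_dir, "cold_counts")
    if (!is.null(concordance)) write_stage_tsv(concordance, cfg$out_dir, "cold_concordance")
    created <- list.files(cfg$out_dir, full.names = TRUE)

    manifest <- list(
      config_hash = config_hash(cfg),
      seed = cfg$seed,
      n_genes = nrow(inputs$matrix),
      n_genes_filtered = nrow(filtered),
      counts = counts
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(regulated = regulated, counts = counts,
                   concordance = concordance, manifest = manifest))
  }, error = function(e) {
    unlink(created)
    stop("cold pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
}
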
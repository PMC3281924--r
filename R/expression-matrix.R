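#' Construct a validated expression matrix
#'
#' The package's substrate is a genes x samples matrix of log2 intensities.
#' Gene ids live in `rownames()`, sample ids in `colnames()`; both must be
#' unique, non-empty, case-sensitive tokens, and every value must be finite.
#'
#' @param values Numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @return The validated matrix (invisibly unchanged).
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids: ", paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ", paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(genes)) || any(!nzchar(samples))) {
    stop("empty gene or sample id", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  values
}

#' Read a tab-delimited expression matrix
#'
#' Canonical dialect: tab-separated text, `#` comment lines ignored, header
#' row of sample ids, first column gene ids, decimal point only. Malformed
#' rows and non-numeric cells are rejected with the offending line named;
#' duplicate gene ids are a validation error.
#'
#' @param path Path to a TSV file.
#' @return A numeric genes x samples matrix (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  if (width < 2) stop("header has no sample columns in ", path, call. = FALSE)
  bad <- which(lengths(fields) != width)
  if (length(bad)) {
    stop("line ", line_no[bad[1]], " has ", lengths(fields)[bad[1]],
         " fields, expected ", width, call. = FALSE)
  }
  samples <- fields[[1]][-1]
  body <- fields[-1]
  genes <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(genes)) {
    stop("duplicate gene id '", genes[duplicated(genes)][1], "' in ", path, call. = FALSE)
  }
  values <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(body, `[`, -1))),
           nrow = length(body), ncol = width - 1L, byrow = TRUE)
  )
  if (anyNA(values)) {
    row <- which(apply(is.na(values), 1, any))[1]
    stop("non-numeric value on line ", line_no[-1][row], " of ", path, call. = FALSE)
  }
  dimnames(values) <- list(genes, samples)
  expression_matrix(values)
}

#' Write an expression matrix as TSV
#'
#' @param m Validated expression matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  m <- expression_matrix(m)
  tb <- tibble::as_tibble(m, rownames = "gene_id")
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Read a sample-design table
#'
#' Expects columns `sample_id`, `tissue`, `stage` (days after fertilization,
#' may be missing for vegetative tissues), `replicate`, `treatment`
#' (`control` or `cold`). Extra columns (e.g. `cultivar`) are kept. A `group`
#' column is derived when absent: the non-missing parts of
#' (cultivar, tissue, stage, treatment) joined with underscores, with
#' `control` suppressed so untreated designs read naturally.
#'
#' @param path TSV file.
#' @return A tibble, one row per sample.
#' @export
read_sample_design <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  validate_sample_design(d)
}

#' @rdname read_sample_design
#' @param design A data frame to validate/augment in place of a file.
#' @export
validate_sample_design <- function(design) {
  d <- tibble::as_tibble(design)
  need <- c("sample_id", "tissue", "replicate", "treatment")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("design lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"stage" %in% names(d)) d$stage <- NA_integer_
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in design", call. = FALSE)
  ok_tissue <- c("root", "leaf", "seedling", "ovary", "embryo", "endosperm", "seed")
  if (!all(d$tissue %in% ok_tissue)) {
    stop("unknown tissue token(s): ",
         paste(setdiff(unique(d$tissue), ok_tissue), collapse = ", "), call. = FALSE)
  }
  if (!all(d$treatment %in% c("control", "cold"))) {
    stop("treatment must be 'control' or 'cold'", call. = FALSE)
  }
  if (any(d$replicate < 1 | d$replicate != round(d$replicate))) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  if (!"group" %in% names(d)) {
    parts <- cbind(
      if ("cultivar" %in% names(d)) d$cultivar else NA_character_,
      d$tissue,
      ifelse(is.na(d$stage), NA_character_, as.character(d$stage)),
      ifelse(d$treatment == "control", NA_character_, d$treatment)
    )
    d$group <- apply(parts, 1, function(p) paste(p[!is.na(p)], collapse = "_"))
  }
  d
}

#' Write a sample-design table as TSV
#' @param design Design tibble.
#' @param path Output file.
#' @export
write_sample_design <- function(design, path) {
  readr::write_tsv(validate_sample_design(design), path)
  invisible(path)
}

#' Check that a matrix and a design describe the same samples
#'
#' Every sample id in the matrix must have exactly one design row.
#' @param m Expression matrix.
#' @param design Design tibble.
#' @return The design, reordered to match `colnames(m)`.
#' @export
align_design <- function(m, design) {
  design <- validate_sample_design(design)
  miss <- setdiff(colnames(m), design$sample_id)
  if (length(miss)) {
    stop("samples missing from design: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  design[match(colnames(m), design$sample_id), , drop = FALSE]
}

# Sample ids belonging to a design group.
group_samples <- function(design, group) {
  design <- validate_sample_design(design)
  unknown <- setdiff(group, design$group)
  if (length(unknown)) {
    stop("unknown group(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  design$sample_id[design$group %in% group]
}
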
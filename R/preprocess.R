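#' Present/Absent detection calls
#'
#' Gene-level stand-in for probe-level detection: a cell is called Present
#' (`"P"`) when its log2 value strictly exceeds the threshold, Absent
#' (`"A"`) otherwise. The threshold is either a per-array quantile (default
#' mode, `q = 0.30`: the cut adapts to each hybridization) or an absolute
#' log2 value (default 6.0). An all-equal array under the quantile rule is
#' all-Absent, since no value strictly exceeds its own quantile.
#'
#' @param m Expression matrix.
#' @param rule List with `mode` (`"quantile"` or `"absolute"`) and `q` or
#'   `threshold`.
#' @return Character matrix of `"P"`/`"A"` with the shape of `m`.
#' @export
detection_call <- function(m, rule = list(mode = "quantile", q = 0.30, threshold = 6.0)) {
  m <- expression_matrix(m)
  mode <- rule$mode %||% "quantile"
  if (mode == "quantile") {
    q <- rule$q %||% 0.30
    if (q <= 0 || q >= 1) stop("detection quantile must be in (0, 1)", call. = FALSE)
    thr <- apply(m, 2, stats::quantile, probs = q, names = FALSE)
  } else if (mode == "absolute") {
    thr <- rep(rule$threshold %||% 6.0, ncol(m))
  } else {
    stop("unknown detection mode: ", mode, call. = FALSE)
  }
  calls <- ifelse(sweep(m, 2, thr, ">"), "P", "A")
  dimnames(calls) <- dimnames(m)
  calls
}

#' Expressed-gene logic over sample groups
#'
#' A gene is expressed in a group iff called Present in *all* replicates of
#' that group, and expressed in a scope (a set of groups) iff expressed in
#' at least one group of the scope.
#'
#' @param calls Detection-call matrix from [detection_call()].
#' @param design Sample design (with a `group` column).
#' @param scope Character vector of group ids; default all groups.
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(calls, design, scope = NULL) {
  design <- validate_sample_design(design)
  miss <- setdiff(colnames(calls), design$sample_id)
  if (length(miss)) {
    stop("samples missing from design: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(scope)) scope <- unique(design$group)
  unknown <- setdiff(scope, design$group)
  if (length(unknown)) stop("unknown group(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  expressed <- rep(FALSE, nrow(calls))
  for (g in scope) {
    cols <- design$sample_id[design$group == g]
    if (length(cols) < 2) stop("group '", g, "' has fewer than 2 replicates", call. = FALSE)
    expressed <- expressed | rowSums(calls[, cols, drop = FALSE] == "P") == length(cols)
  }
  rownames(calls)[expressed]
}

#' Percentage reporting for expressed-gene counts
#'
#' Rounds the share of a subset among detected genes to a whole percentage,
#' the precision used in printed summaries (e.g. genes expressed in seed as
#' a share of all detected genes).
#'
#' @param n_subset,n_total Gene counts.
#' @return Integer percentage.
#' @export
expressed_percentage <- function(n_subset, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  round(100 * n_subset / n_total)
}

#' Quantile normalization of an expression matrix
#'
#' Forces every column onto the common distribution given by the row-wise
#' mean of the sorted columns; within-column ranks are preserved and ties
#' are resolved by averaging the bracketing target values. Idempotent.
#'
#' @param m Expression matrix with at least 2 samples (a single-column
#'   matrix is returned unchanged with a warning).
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- expression_matrix(m)
  if (ncol(m) < 2) {
    warning("single-column matrix: quantile normalization is a no-op")
    return(m)
  }
  target <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) {
    r <- rank(x, ties.method = "average")
    (target[floor(r)] + target[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Gene-wise Z-scoring
#'
#' Per gene: `(x - mean) / sd` with the sample (n-1) standard deviation;
#' constant genes map to all-zeros rather than erroring.
#'
#' @param m Expression matrix with at least 2 samples.
#' @return Z-scored matrix.
#' @export
zscore_by_gene <- function(m) {
  m <- expression_matrix(m)
  if (ncol(m) < 2) stop("need at least 2 samples to Z-score", call. = FALSE)
  mu <- rowMeans(m)
  sdev <- apply(m, 1, stats::sd)
  out <- (m - mu) / ifelse(sdev > 0, sdev, 1)
  out[sdev == 0, ] <- 0
  dimnames(out) <- dimnames(m)
  out
}

#' Replicate quality control by Pearson correlation
#'
#' For every sample group with exactly two replicate arrays, the Pearson
#' correlation between the replicates over all genes. Groups with a
#' different replicate count are skipped with a warning.
#'
#' @param m Expression matrix.
#' @param design Sample design.
#' @return Tibble of class `replicate_qc` with columns `group`, `tissue`,
#'   `stage`, `treatment`, `pcc`.
#' @export
replicate_qc <- function(m, design) {
  design <- align_design(m, design)
  rows <- list()
  for (g in unique(design$group)) {
    d <- design[design$group == g, ]
    if (nrow(d) != 2) {
      warning("group '", g, "' has ", nrow(d), " replicates, skipped")
      next
    }
    rows[[g]] <- tibble::tibble(
      group = g, tissue = d$tissue[1], stage = d$stage[1], treatment = d$treatment[1],
      pcc = stats::cor(m[, d$sample_id[1]], m[, d$sample_id[2]])
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("replicate_qc", class(out))
  out
}

#' Drop low-expression genes
#'
#' Mode `"all_absent"` drops genes called Absent in every sample (very low
#' intensity through all hybridizations); mode `"negative"` drops genes
#' whose maximum log2 value is below zero.
#'
#' @param m Expression matrix.
#' @param calls Detection calls (required for mode `"all_absent"`).
#' @param mode `"all_absent"` or `"negative"`.
#' @return The filtered matrix.
#' @export
filter_low_expression <- function(m, calls = NULL, mode = c("all_absent", "negative")) {
  m <- expression_matrix(m)
  mode <- match.arg(mode)
  if (mode == "all_absent") {
    if (is.null(calls)) stop("mode 'all_absent' needs detection calls", call. = FALSE)
    if (!identical(dim(calls), dim(m))) stop("calls shape does not match matrix", call. = FALSE)
    keep <- rowSums(calls == "P") > 0
  } else {
    keep <- apply(m, 1, max) >= 0
  }
  m[keep, , drop = FALSE]
}
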
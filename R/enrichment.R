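# Closed-form Pearson chi-square for a 2x2 table (no continuity correction):
# chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)). Degenerate margins give 0.
chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  ifelse(denom > 0, n * (a * d - b * c)^2 / denom, 0)
}

# Minimum expected cell count of the 2x2 table, for the small-sample flag.
min_expected_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  rows <- c(a + b, c + d)
  cols <- c(a + c, b + d)
  min(outer(rows, cols) / n)
}

#' Chi-square over-representation of categories in a gene set
#'
#' For each term, the 2x2 contingency of set membership against term
#' membership over the background: `a` genes in both, out of `n` set genes,
#' `K` term genes, `N` background genes. Pearson chi-square without
#' continuity correction (df = 1), upper-tail p, `-log10(p)`, and BH-FDR
#' across the tested terms. Terms with any expected count below 5 are
#' flagged (`expected_low`); with `exact_fallback = TRUE` those terms use
#' Fisher's exact test instead. A term is `enriched` iff `a/n > K/N`.
#'
#' @param geneset Character vector, a subset of the background.
#' @param cats A [category_map()].
#' @param exact_fallback Use Fisher's exact p when an expected count is < 5.
#' @return Tibble of class `enrichment_result`: `term`, `label`, `a`, `n`,
#'   `K`, `N`, `chi2`, `p`, `neglog10p`, `q`, `expected_low`, `enriched`.
#' @export
chisq_enrichment <- function(geneset, cats, exact_fallback = FALSE) {
  stopifnot(inherits(cats, "category_map"))
  geneset <- unique(geneset)
  if (length(geneset) == 0) stop("empty gene set", call. = FALSE)
  bg <- cats$background
  if (length(bg) < 2) stop("background needs at least 2 genes", call. = FALSE)
  outside <- setdiff(geneset, bg)
  if (length(outside)) {
    stop("gene set not a subset of the background (", length(outside),
         " genes outside)", call. = FALSE)
  }
  n <- length(geneset)
  N <- length(bg)
  rows <- purrr::map(names(cats$terms), function(id) {
    members <- cats$terms[[id]]
    K <- length(members)
    if (K == 0) {
      warning("term '", id, "' has no background genes, skipped")
      return(NULL)
    }
    a <- length(intersect(geneset, members))
    b <- n - a
    cc <- K - a
    d <- N - n - cc
    chi2 <- chisq_2x2(a, b, cc, d)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    low <- min_expected_2x2(a, b, cc, d) < 5
    if (low && exact_fallback) {
      p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    }
    tibble::tibble(
      term = id, label = unname(cats$labels[id]), a = a, n = n, K = K, N = N,
      chi2 = chi2, p = p, expected_low = low,
      enriched = a / n > K / N
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) stop("no testable terms", call. = FALSE)
  out$p <- pmin(pmax(out$p, .Machine$double.xmin), 1)
  out$neglog10p <- -log10(out$p)
  out$q <- bh_fdr(out$p)
  out <- out[, c("term", "label", "a", "n", "K", "N", "chi2", "p",
                 "neglog10p", "q", "expected_low", "enriched")]
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Assemble a terms x gene-sets matrix of -log10 p
#'
#' Rows are terms, columns the named gene sets; a cell carries `-log10(p)`
#' when the term was tested and enriched in that set, and `NA` (rendered as
#' `"-"` on disk) otherwise — the "not enriched" marker of printed
#' enrichment tables. Terms enriched in no set are dropped with a warning.
#'
#' @param results Named list of `enrichment_result` tibbles computed on the
#'   same category map.
#' @param terms Optional term subset/order.
#' @return Tibble of class `enrichment_matrix`: `term`, `label`, one column
#'   per gene-set name.
#' @export
enrichment_matrix <- function(results, terms = NULL) {
  stopifnot(length(names(results)) == length(results))
  long <- dplyr::bind_rows(
    purrr::imap(results, function(r, nm) {
      tibble::tibble(term = r$term, label = r$label, set = nm,
                     value = ifelse(r$enriched, r$neglog10p, NA_real_))
    })
  )
  if (!is.null(terms)) long <- long[long$term %in% terms, ]
  wide <- tidyr::pivot_wider(long, id_cols = c("term", "label"),
                             names_from = "set", values_from = "value")
  value_cols <- setdiff(names(wide), c("term", "label"))
  empty <- rowSums(!is.na(wide[, value_cols, drop = FALSE])) == 0
  if (any(empty)) {
    warning(sum(empty), " term(s) enriched in no gene set dropped")
    wide <- wide[!empty, ]
  }
  if (!is.null(terms)) wide <- wide[order(match(wide$term, terms)), ]
  class(wide) <- c("enrichment_matrix", class(wide))
  wide
}

#' Write / read an enrichment matrix as TSV (with "-" as the marker)
#' @param x An `enrichment_matrix` tibble.
#' @param path File path.
#' @export
write_enrichment_matrix <- function(x, path) {
  readr::write_tsv(x, path, na = "-")
  invisible(path)
}

#' @rdname write_enrichment_matrix
#' @export
read_enrichment_matrix <- function(path) {
  out <- readr::read_tsv(path, na = "-", comment = "#", show_col_types = FALSE)
  class(out) <- c("enrichment_matrix", class(out))
  out
}

#' TF-family over-representation within TF gene sets
#'
#' Identical statistics to [chisq_enrichment()], computed with a background
#' restricted to transcription-factor genes (family membership against the
#' TF universe).
#'
#' @param tf_sets Named list of TF gene-id vectors.
#' @param family_map A [category_map()] whose background is the TF universe.
#' @param ... Passed to [chisq_enrichment()].
#' @return Named list of `enrichment_result` tibbles.
#' @export
family_enrichment <- function(tf_sets, family_map, ...) {
  stopifnot(length(names(tf_sets)) == length(tf_sets))
  purrr::map(tf_sets, chisq_enrichment, cats = family_map, ...)
}
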
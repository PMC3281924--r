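#' Pearson correlation profiles of TFs against a compendium
#'
#' Standard Pearson correlation across arrays between each transcription
#' factor and every other gene in the compendium. Genes with zero variance
#' across arrays are excluded with a warning; a TF's self-correlation is
#' set to `NA` so it never enters its own neighborhood.
#'
#' @param compendium Expression matrix (genes x arrays), already filtered
#'   of genes with very low intensity through all hybridizations (see
#'   [filter_low_expression()]); needs >= 3 arrays.
#' @param tfs Character vector of TF gene ids present in the matrix.
#' @return Numeric matrix (TFs x genes) of correlations.
#' @export
pcc_profiles <- function(compendium, tfs) {
  m <- expression_matrix(compendium)
  if (ncol(m) < 3) stop("need at least 3 arrays", call. = FALSE)
  miss <- setdiff(tfs, rownames(m))
  if (length(miss)) {
    stop("TF gene(s) absent from matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) excluded from correlation")
    if (any(tfs %in% rownames(m)[sds == 0])) {
      stop("zero-variance TF(s): ",
           paste(intersect(tfs, rownames(m)[sds == 0]), collapse = ", "), call. = FALSE)
    }
    m <- m[sds > 0, , drop = FALSE]
  }
  prof <- stats::cor(t(m[tfs, , drop = FALSE]), t(m))
  for (tf in tfs) prof[tf, tf] <- NA_real_
  prof
}

#' Top-k co-expression neighborhoods
#'
#' The k genes most positively correlated with each TF, strictly ordered by
#' descending correlation with ties broken by ascending gene id — the
#' deterministic "top related genes" used for guilt-by-association
#' annotation. Fewer than k candidates yields all of them with a warning.
#'
#' @param profiles TF x gene correlation matrix from [pcc_profiles()].
#' @param k Neighborhood size (default 500).
#' @return Tibble of class `coexpression_neighborhood`: `tf`, `rank`,
#'   `gene`, `pcc`.
#' @export
top_k_neighborhood <- function(profiles, k = 500) {
  rows <- lapply(rownames(profiles), function(tf) {
    pcc <- profiles[tf, ]
    pcc <- pcc[!is.na(pcc)]
    ord <- order(-pcc, names(pcc))
    if (length(ord) < k) {
      warning("TF '", tf, "': only ", length(ord), " candidates for k = ", k)
    }
    take <- utils::head(ord, k)
    tibble::tibble(tf = tf, rank = seq_along(take),
                   gene = names(pcc)[take], pcc = unname(pcc[take]))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("coexpression_neighborhood", class(out))
  out
}

#' Guilt-by-association annotation of TF neighborhoods
#'
#' Chi-square over-representation of each category in every TF's top-k
#' neighborhood against the compendium background, with BH-FDR per TF.
#' Empty neighborhoods are skipped with a warning.
#'
#' @param nbhd A `coexpression_neighborhood` from [top_k_neighborhood()].
#' @param cats A [category_map()] whose background is the compendium genes.
#' @return Tibble of class `tf_annotation`: per TF, the full
#'   [chisq_enrichment()] columns prefixed by `tf`.
#' @export
annotate_tf <- function(nbhd, cats) {
  rows <- lapply(split(nbhd$gene, nbhd$tf), function(genes) genes)
  out <- purrr::imap(rows, function(genes, tf) {
    if (!length(genes)) {
      warning("TF '", tf, "' has an empty neighborhood, skipped")
      return(NULL)
    }
    res <- chisq_enrichment(genes, cats)
    dplyr::mutate(tibble::as_tibble(res), tf = tf, .before = 1)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("tf_annotation", class(out))
  out
}

#' Build the bipartite TF-function network
#'
#' TF nodes carry their seed expression class (embryo / endosperm / both /
#' unclassified), term nodes their labels, and an edge links a TF to every
#' term enriched in its neighborhood at `q < q_max`. TFs with no surviving
#' term remain as isolated nodes.
#'
#' @param annotations A `tf_annotation` tibble from [annotate_tf()].
#' @param tf_classes Optional `predominance_call` tibble (or any tibble
#'   with `gene` and `class`) supplying TF expression classes.
#' @param q_max Edge threshold on the per-TF FDR (default 0.05).
#' @return A [tf_network()] igraph; export with [write_network()].
#' @export
build_network <- function(annotations, tf_classes = NULL, q_max = 0.05) {
  keep <- annotations[annotations$enriched & annotations$q < q_max, ]
  tfs <- tibble::tibble(tf = unique(annotations$tf))
  tfs$class <- "unclassified"
  if (!is.null(tf_classes)) {
    idx <- match(tfs$tf, tf_classes$gene)
    tfs$class <- ifelse(is.na(idx), "unclassified", tf_classes$class[idx])
  }
  terms <- unique(keep[, c("term", "label")])
  edges <- tibble::tibble(tf = keep$tf, term = keep$term, q = keep$q)
  tf_network(tfs, terms, edges)
}
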
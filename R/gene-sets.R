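#' Construct a category map
#'
#' Holds term -> gene-set annotations (GO terms, TF families, planted module
#' labels) against an explicit background universe. Every term's gene set is
#' forced to be a subset of the background.
#'
#' @param terms Named list of character vectors (term id -> gene ids).
#' @param background Character vector: the gene universe.
#' @param labels Optional named character vector of term descriptions.
#' @return An object of class `category_map`.
#' @export
category_map <- function(terms, background, labels = NULL) {
  if (length(background) == 0) stop("empty background", call. = FALSE)
  background <- unique(as.character(background))
  if (is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stop("every term needs a non-empty id", call. = FALSE)
  }
  terms <- lapply(terms, function(g) unique(as.character(g)))
  dropped <- sum(vapply(terms, function(g) sum(!g %in% background), integer(1)))
  if (dropped > 0) {
    message(dropped, " gene(s) outside the background dropped from term sets")
    terms <- lapply(terms, function(g) g[g %in% background])
  }
  if (is.null(labels)) labels <- stats::setNames(names(terms), names(terms))
  labels <- labels[names(terms)]
  labels[is.na(labels)] <- names(terms)[is.na(labels)]
  names(labels) <- names(terms)
  structure(list(terms = terms, labels = labels, background = background),
            class = "category_map")
}

#' @export
print.category_map <- function(x, ...) {
  cat("<category_map> ", length(x$terms), " terms over ",
      length(x$background), " background genes\n", sep = "")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one term per line, fields `term<TAB>description<TAB>gene...`.
#' Genes absent from the background are dropped (count reported via
#' `message()`); an empty term id is a validation error.
#'
#' @param path GMT file.
#' @param background Character vector, the gene universe.
#' @return A [category_map()].
#' @export
read_gene_sets <- function(path, background) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1)
  if (any(!nzchar(trimws(ids)))) {
    stop("empty term id on line ", which(!nzchar(trimws(ids)))[1], " of ", path,
         call. = FALSE)
  }
  labels <- vapply(fields, function(f) if (length(f) >= 2) f[[2]] else "", character(1))
  terms <- lapply(fields, function(f) if (length(f) > 2) f[-(1:2)] else character(0))
  names(terms) <- ids
  category_map(terms, background, labels = stats::setNames(labels, ids))
}

#' Write a category map in GMT format
#' @param cats A [category_map()].
#' @param path Output file.
#' @export
write_gene_sets <- function(cats, path) {
  stopifnot(inherits(cats, "category_map"))
  lines <- vapply(names(cats$terms), function(id) {
    paste(c(id, cats$labels[[id]], cats$terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a validated IUPAC motif library
#'
#' @param motifs Either a data frame with columns `motif_id` and `pattern`
#'   (optional `description`), or a named character vector of patterns.
#' @return A tibble with class `motif_library`. Patterns must use the
#'   15-letter IUPAC nucleotide alphabet and be at least 4 nt long.
#' @export
motif_library <- function(motifs) {
  if (is.character(motifs) && !is.null(names(motifs))) {
    motifs <- tibble::tibble(motif_id = names(motifs), pattern = unname(motifs))
  }
  tb <- tibble::as_tibble(motifs)
  if (!all(c("motif_id", "pattern") %in% names(tb))) {
    stop("motif library needs columns motif_id and pattern", call. = FALSE)
  }
  if (anyDuplicated(tb$motif_id)) stop("duplicate motif ids", call. = FALSE)
  tb$pattern <- toupper(tb$pattern)
  bad_chr <- !grepl("^[ACGTRYSWKMBDHVN]+$", tb$pattern)
  if (any(bad_chr)) {
    stop("pattern with illegal character: ", tb$pattern[bad_chr][1], call. = FALSE)
  }
  if (any(nchar(tb$pattern) < 4)) stop("motif patterns must be >= 4 nt", call. = FALSE)
  class(tb) <- c("motif_library", class(tb))
  tb
}

#' Read a motif library from TSV
#'
#' Columns: `motif_id`, `pattern`, optional `description`; `#` comments
#' allowed.
#' @param path TSV file.
#' @return A [motif_library()] tibble.
#' @export
read_motif_library <- function(path) {
  motif_library(readr::read_tsv(path, comment = "#", show_col_types = FALSE))
}
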
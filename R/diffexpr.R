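#' @importFrom rlang %||%
NULL

#' Analysis thresholds
#'
#' The stringency settings used throughout: tissue-predominance at
#' FDR-adjusted p < 0.0005 with linear fold change > 2 (log2 fold > 1),
#' time-course regulation at raw p < 0.001, cold regulation at raw p < 0.05
#' with fold > 2, top-500 co-expression neighborhoods, 3000-nt promoters,
#' and motif enrichment at FDR < 0.05.
#'
#' @param ... Named overrides of individual thresholds.
#' @return A named list.
#' @export
default_thresholds <- function(...) {
  th <- list(
    predominant_q = 5e-4, predominant_lfc = 1,
    timecourse_p = 1e-3,
    cold_p = 0.05, cold_lfc = 1,
    k_neighborhood = 500L,
    promoter_length = 3000L,
    motif_fdr = 0.05
  )
  utils::modifyList(th, list(...))
}

#' Two-group contrast fit
#'
#' Per gene: contrast estimate `mean(groupA) - mean(groupB)`, pooled
#' within-group variance `s_g^2` with `d_g = nA + nB - 2` degrees of
#' freedom, and the standard-error factor `v = 1/nA + 1/nB`. Feed the result
#' to [moderate()] for empirical-Bayes inference.
#'
#' @param m Expression matrix.
#' @param group_a,group_b Sample-id vectors (or group ids resolved through
#'   `design`). Must be disjoint, each with >= 2 samples.
#' @param design Optional sample design for resolving group ids.
#' @return Tibble of class `contrast_fit`: `gene`, `estimate`, `s2`, `df`,
#'   with the scalar `v` as an attribute.
#' @export
fit_contrast <- function(m, group_a, group_b, design = NULL) {
  m <- expression_matrix(m)
  resolve <- function(g) {
    if (!is.null(design) && all(g %in% validate_sample_design(design)$group)) {
      group_samples(design, g)
    } else g
  }
  a <- resolve(group_a)
  b <- resolve(group_b)
  miss <- setdiff(c(a, b), colnames(m))
  if (length(miss)) stop("samples not in matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  if (length(intersect(a, b))) stop("contrast groups overlap", call. = FALSE)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples", call. = FALSE)
  ma <- rowMeans(m[, a, drop = FALSE])
  mb <- rowMeans(m[, b, drop = FALSE])
  ssa <- rowSums((m[, a, drop = FALSE] - ma)^2)
  ssb <- rowSums((m[, b, drop = FALSE] - mb)^2)
  out <- tibble::tibble(
    gene = rownames(m),
    estimate = unname(ma - mb),
    s2 = unname((ssa + ssb) / (na + nb - 2)),
    df = na + nb - 2
  )
  attr(out, "v") <- 1 / na + 1 / nb
  class(out) <- c("contrast_fit", class(out))
  out
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used for moment-matching the variance-prior degrees of freedom.
trigamma_inverse <- function(x, tol = 1e-8, maxit = 50) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in seq_len(maxit)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < tol) break
  }
  y
}

#' Empirical-Bayes moderation of a contrast fit
#'
#' Shrinks gene-wise variances toward a pooled prior before forming
#' t-statistics. Marginally `s_g^2 ~ s0^2 F(d_g, d0)`; writing
#' `e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)`, the prior
#' hyperparameters solve `mean(e) = log s0^2 - digamma(d0/2) + log(d0/2)`
#' and `var(e) = trigamma(d_g/2) + trigamma(d0/2)`, the latter by trigamma
#' inversion (Newton, tolerance 1e-8). The posterior variance is
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and the moderated t is
#' referred to a t-distribution on `d_g + d0` degrees of freedom. When the
#' observed log-variances are less dispersed than sampling alone predicts,
#' `d0` is infinite and every gene uses the common prior variance.
#'
#' Genes with exactly zero sample variance are given a floor variance of
#' 1e-8; if *all* variances are zero the fit degenerates to ordinary t on
#' the floor variance with a warning.
#'
#' @param fit A `contrast_fit` from [fit_contrast()] (needs >= 50 genes for
#'   stable hyperparameter estimation).
#' @return Tibble of class `moderated_contrast`: `gene`, `estimate`, `s2`,
#'   `df`, `s2_post`, `t`, `p`, `q`; hyperparameters `d0` and `s0sq` are
#'   attributes (see [glance.moderated_contrast()]).
#' @export
moderate <- function(fit) {
  stopifnot(inherits(fit, "contrast_fit"))
  if (nrow(fit) < 50) {
    stop("need at least 50 genes to estimate the variance prior", call. = FALSE)
  }
  v <- attr(fit, "v")
  s2 <- fit$s2
  dg <- fit$df
  if (all(s2 == 0)) {
    warning("all gene variances are zero; falling back to a floor variance")
    s2 <- rep(1e-8, length(s2))
    t_stat <- fit$estimate / sqrt(s2 * v)
    p <- 2 * stats::pt(-abs(t_stat), df = dg)
    out <- dplyr::mutate(tibble::as_tibble(fit), s2_post = s2, t = t_stat,
                         p = p, q = bh_fdr(p))
    attr(out, "d0") <- NA_real_
    attr(out, "s0sq") <- 1e-8
    class(out) <- c("moderated_contrast", class(out))
    return(out)
  }
  if (any(s2 == 0)) s2[s2 == 0] <- 1e-8

  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - mean(trigamma(dg / 2))
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(emean)
  }
  s2_post <- if (is.finite(d0)) (d0 * s0sq + dg * s2) / (d0 + dg) else rep(s0sq, length(s2))
  t_stat <- fit$estimate / sqrt(s2_post * v)
  df_total <- dg + d0
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  out <- dplyr::mutate(tibble::as_tibble(fit),
                       s2_post = s2_post, t = t_stat, p = p, q = bh_fdr(p))
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  attr(out, "v") <- v
  class(out) <- c("moderated_contrast", class(out))
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} m p_(j) / j` on the sorted scale, mapped back to
#' the input order and capped at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Tissue-predominance calls from two moderated contrasts
#'
#' A gene passes for a tissue iff `q < predominant_q` and
#' `log2FC > predominant_lfc` (positive direction = higher in the seed
#' tissue). Passing both single-tissue criteria gives class `"both"`, one
#' gives that tissue, none gives `"none"`.
#'
#' @param embryo_result,endosperm_result `moderated_contrast` tibbles over
#'   the same gene universe (tissue vs reference tissues).
#' @param thresholds See [default_thresholds()].
#' @return Tibble `gene`, `class` with class `predominance_call`.
#' @export
call_predominant <- function(embryo_result, endosperm_result,
                             thresholds = default_thresholds()) {
  if (!setequal(embryo_result$gene, endosperm_result$gene)) {
    stop("contrasts cover different gene universes", call. = FALSE)
  }
  en <- endosperm_result[match(embryo_result$gene, endosperm_result$gene), ]
  pass <- function(r) r$q < thresholds$predominant_q & r$estimate > thresholds$predominant_lfc
  pe <- pass(embryo_result)
  pn <- pass(en)
  out <- tibble::tibble(
    gene = embryo_result$gene,
    class = dplyr::case_when(pe & pn ~ "both", pe ~ "embryo", pn ~ "endosperm",
                             TRUE ~ "none")
  )
  class(out) <- c("predominance_call", class(out))
  out
}

#' One-way ANOVA over developmental stages
#'
#' Fixed-effects F test of equal stage means within one tissue, computed
#' gene-wise from group sums of squares. The trend direction is the sign of
#' `mean(last stage) - mean(first stage)` (meaningful for genes passing the
#' p threshold). Zero between- and within-stage variance gives F = 0 and
#' p = 1 by convention; zero within-group variance with real separation
#' gives p = 0.
#'
#' @param m Expression matrix.
#' @param design Sample design.
#' @param tissue Tissue whose staged groups are tested (needs >= 3 stages,
#'   each with >= 2 replicates).
#' @return Tibble of class `timecourse_fit`: `gene`, `f`, `p`, `delta`
#'   (last minus first stage mean), `direction`.
#' @export
anova_timecourse <- function(m, design, tissue) {
  m <- expression_matrix(m)
  design <- align_design(m, design)
  d <- design[design$tissue == tissue & !is.na(design$stage), ]
  stages <- sort(unique(d$stage))
  if (length(stages) < 3) stop("need at least 3 stages for the time-course test", call. = FALSE)
  cols_by_stage <- lapply(stages, function(s) d$sample_id[d$stage == s])
  if (any(lengths(cols_by_stage) < 2)) {
    stop("every stage needs at least 2 replicates", call. = FALSE)
  }
  k <- length(stages)
  n_i <- lengths(cols_by_stage)
  n <- sum(n_i)
  sub <- m[, unlist(cols_by_stage), drop = FALSE]
  grand <- rowMeans(sub)
  means <- matrix(vapply(cols_by_stage, function(cc) rowMeans(m[, cc, drop = FALSE]),
                         numeric(nrow(m))),
                  nrow = nrow(m), ncol = k)
  ssb <- as.numeric((means - grand)^2 %*% n_i)
  ssw <- numeric(nrow(m))
  for (j in seq_len(k)) {
    cc <- cols_by_stage[[j]]
    ssw <- ssw + rowSums((m[, cc, drop = FALSE] - means[, j])^2)
  }
  dfb <- k - 1
  dfw <- n - k
  msb <- ssb / dfb
  msw <- ssw / dfw
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  p <- ifelse(is.infinite(f), 0,
              ifelse(msw > 0, stats::pf(f, dfb, dfw, lower.tail = FALSE), 1))
  delta <- means[, k] - means[, 1]
  out <- tibble::tibble(
    gene = rownames(m), f = unname(f), p = unname(p), delta = unname(delta),
    direction = unname(ifelse(delta >= 0, "up", "down"))
  )
  attr(out, "tissue") <- tissue
  attr(out, "stages") <- stages
  class(out) <- c("timecourse_fit", class(out))
  out
}

#' Cold-regulated gene sets from treated/control pairs
#'
#' For each pair, a moderated contrast of treated minus control; `up` genes
#' have `p < cold_p` and `log2FC > cold_lfc` (higher in the treated/later
#' group), `down` genes the mirror image.
#'
#' @param m Expression matrix.
#' @param design Sample design.
#' @param pairs Named list; each element a character vector with entries
#'   `treated` and `control` naming design groups (or sample-id vectors in
#'   a 2-element list of the same names).
#' @param thresholds See [default_thresholds()].
#' @return Tibble of class `cold_call`: `pair`, `gene`, `estimate`, `p`,
#'   `q`, `direction` (regulated genes only); per-pair counts in
#'   `attr(, "counts")`, the full fits in `attr(, "fits")`.
#' @export
call_cold_regulated <- function(m, design, pairs, thresholds = default_thresholds()) {
  out <- list()
  fits <- list()
  for (nm in names(pairs)) {
    pr <- pairs[[nm]]
    res <- moderate(fit_contrast(m, pr[["treated"]], pr[["control"]], design = design))
    fits[[nm]] <- res
    reg <- res[res$p < thresholds$cold_p & abs(res$estimate) > thresholds$cold_lfc, ]
    if (nrow(reg)) {
      out[[nm]] <- tibble::tibble(
        pair = nm, gene = reg$gene, estimate = reg$estimate, p = reg$p, q = reg$q,
        direction = ifelse(reg$estimate > 0, "up", "down")
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(pair = character(0), gene = character(0),
                          estimate = numeric(0), p = numeric(0), q = numeric(0),
                          direction = character(0))
  }
  counts <- tidyr::complete(
    dplyr::count(res, .data$pair, .data$direction),
    pair = names(pairs), direction = c("up", "down"), fill = list(n = 0L)
  )
  attr(res, "counts") <- counts
  attr(res, "fits") <- fits
  class(res) <- c("cold_call", class(res))
  res
}

#' Trend concordance between two regulated-gene sets
#'
#' Intersects two gene -> direction maps and reports the fraction of common
#' genes regulated in the same direction (the cross-dataset or
#' seed-vs-seedling comparison). With no common genes the fraction is `NA`.
#'
#' @param set_a,set_b Tibbles with columns `gene` and `direction`
#'   (`"up"`/`"down"`), or named character vectors of directions.
#' @return List with `common` (tibble `gene`, `direction_a`, `direction_b`,
#'   `same`), `n_common`, `fraction_same`.
#' @export
trend_concordance <- function(set_a, set_b) {
  as_map <- function(s) {
    if (is.data.frame(s)) stats::setNames(s$direction, s$gene) else s
  }
  a <- as_map(set_a)
  b <- as_map(set_b)
  if (!all(c(a, b) %in% c("up", "down"))) {
    stop("directions must be 'up' or 'down'", call. = FALSE)
  }
  common <- intersect(names(a), names(b))
  tb <- tibble::tibble(
    gene = common,
    direction_a = unname(a[common]),
    direction_b = unname(b[common])
  )
  tb$same <- tb$direction_a == tb$direction_b
  list(
    common = tb,
    n_common = nrow(tb),
    fraction_same = if (nrow(tb)) mean(tb$same) else NA_real_
  )
}
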
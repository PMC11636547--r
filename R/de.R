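#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over genes (restricted to genes
#' with a finite log geometric mean across samples and a positive count in
#' that sample) of the ratio of the sample's count to the gene's geometric
#' mean. This is the standard library-size normalization for NB count data.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Positive numeric vector, one factor per sample (named when the
#'   matrix has column names).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    stop("no gene has a nonzero count in every sample; cannot normalize")
  }
  sf <- apply(counts, 2L, function(col) {
    r <- (log(col) - log_geo)[usable & col > 0]
    if (length(r) == 0L) stop("a sample shares no nonzero gene with the geometric-mean set")
    exp(stats::median(r))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  sf
}

# Common NB dispersion for a contrast: ratio-of-sums moment estimator
# sum(s^2 - ybar) / sum(ybar^2) over genes whose pooled mean lies in the
# central 90% (robust to the extremes of the mean distribution, nearly
# unbiased for a shared alpha), floored at 1e-8.
.common_dispersion <- function(y1, y0) {
  n1 <- ncol(y1); n0 <- ncol(y0)
  m1 <- rowMeans(y1); m0 <- rowMeans(y0)
  v1 <- apply(y1, 1L, stats::var)
  v0 <- apply(y0, 1L, stats::var)
  s2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / (n1 + n0 - 2L)
  ybar <- (n1 * m1 + n0 * m0) / (n1 + n0)
  ok <- is.finite(s2) & ybar > 0
  q <- stats::quantile(ybar[ok], c(0.05, 0.95), names = FALSE)
  sel <- ok & ybar >= q[1L] & ybar <= q[2L]
  if (!any(sel)) sel <- ok
  max(sum(s2[sel] - ybar[sel]) / sum(ybar[sel]^2), 1e-8)
}

#' Negative-binomial Wald test for one contrast
#'
#' A deliberately simple DE stage: counts are scaled by median-of-ratios size
#' factors; per gene, the log2 ratio of pseudo-counted group means
#' (pseudo-count 0.5) is tested with a Wald statistic whose standard error
#' comes from the delta method under an NB variance `mu + alpha * mu^2`.
#' By default one common dispersion per contrast is estimated by a pooled
#' (ratio-of-sums) within-group moment estimator over the genes in the
#' central 90% of pooled means, which keeps the test calibrated at small
#' group sizes; `dispersion = "gene"` uses the raw per-gene moment estimate
#' instead. There is no GLM fitting, no empirical
#' Bayes shrinkage and no independent filtering.
#'
#' @param counts Non-negative integer matrix, genes x samples, with column
#'   names matching `names(group_of)`.
#' @param group_of Named character vector mapping sample -> group label.
#' @param contrast Length-2 character vector `c(group, reference)`.
#' @param dispersion `"common"` (default) or `"gene"`.
#' @param sf Optional precomputed size factors for all columns of `counts`;
#'   by default computed on the full matrix.
#' @return A `de_table` data frame: `gene_id`, `group`, `reference`,
#'   `base_mean`, `log2fc`, `p_raw`, `p_adj` (NA; filled by [bh_adjust()] via
#'   [classify_de()] or explicitly), `status` (`"na"` for all-zero genes,
#'   otherwise `"ns"` until classified).
#' @export
nb_wald_test <- function(counts, group_of, contrast,
                         dispersion = c("common", "gene"), sf = NULL) {
  dispersion <- match.arg(dispersion)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  if (!all(colnames(counts) %in% names(group_of))) {
    stop("every sample must appear in 'group_of'")
  }
  stopifnot(length(contrast) == 2L)
  grp <- group_of[colnames(counts)]
  idx1 <- which(grp == contrast[[1L]])
  idx0 <- which(grp == contrast[[2L]])
  if (length(idx1) < 2L || length(idx0) < 2L) {
    stop("both contrast groups need >=2 samples (got ",
         length(idx1), " and ", length(idx0), ")")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  y <- sweep(counts, 2L, sf, "/")
  y1 <- y[, idx1, drop = FALSE]
  y0 <- y[, idx0, drop = FALSE]
  n1 <- length(idx1); n0 <- length(idx0)
  m1 <- rowMeans(y1); m0 <- rowMeans(y0)
  q1 <- m1 + 0.5; q0 <- m0 + 0.5
  log2fc <- log2(q1) - log2(q0)  # exact antisymmetry under contrast swap

  if (dispersion == "common") {
    alpha <- rep(.common_dispersion(y1, y0), nrow(counts))
  } else {
    v1 <- apply(y1, 1L, stats::var)
    v0 <- apply(y0, 1L, stats::var)
    s2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / (n1 + n0 - 2L)
    ybar <- (n1 * m1 + n0 * m0) / (n1 + n0)
    alpha <- pmax((s2 - ybar) / ybar^2, 1e-8)
    alpha[!is.finite(alpha)] <- 1e-8
  }

  # Var(group mean of normalized counts), NB variance propagated through 1/sf
  inv1 <- sum(1 / sf[idx1]); inv0 <- sum(1 / sf[idx0])
  var_m1 <- (q1 * inv1 + n1 * alpha * q1^2) / n1^2
  var_m0 <- (q0 * inv0 + n0 * alpha * q0^2) / n0^2
  se <- sqrt(var_m1 / q1^2 + var_m0 / q0^2) / log(2)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))

  all_zero <- rowSums(counts[, c(idx1, idx0), drop = FALSE]) == 0L
  p[all_zero] <- NA_real_
  log2fc[all_zero] <- NA_real_
  out <- data.frame(
    gene_id = if (is.null(rownames(counts))) paste0("g", seq_len(nrow(counts)))
              else rownames(counts),
    group = contrast[[1L]],
    reference = contrast[[2L]],
    base_mean = rowMeans(y),
    log2fc = log2fc,
    p_raw = p,
    p_adj = NA_real_,
    status = ifelse(all_zero, "na", "ns"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`) with input
#' validation; NAs pass through.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify genes as up / down / ns at an adjusted-p threshold
#'
#' Fills `p_adj` by BH over the contrast's non-NA raw p-values (the family is
#' all testable genes of one contrast) and sets `status`: `up` when
#' `p_adj < alpha` and `log2fc > 0`, `down` when `p_adj < alpha` and
#' `log2fc < 0`, otherwise `ns`; all-zero genes stay `na`.
#'
#' @param de A `de_table` from [nb_wald_test()] (or [read_de_table()] with a
#'   `p_adj` column already present, in which case BH is skipped).
#' @param alpha Adjusted-p threshold; default 0.01.
#' @return The table with `p_adj` and `status` filled.
#' @export
classify_de <- function(de, alpha = 0.01) {
  stopifnot(is.data.frame(de), all(c("log2fc", "p_raw") %in% names(de)))
  if (!"p_adj" %in% names(de) || all(is.na(de$p_adj))) {
    de$p_adj <- bh_adjust(de$p_raw)
  }
  de$status <- ifelse(
    is.na(de$p_adj) | is.na(de$log2fc), "na",
    ifelse(de$p_adj < alpha & de$log2fc > 0, "up",
           ifelse(de$p_adj < alpha & de$log2fc < 0, "down", "ns"))
  )
  de
}
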
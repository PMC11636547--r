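#' Kruskal-Wallis omnibus test
#'
#' Rank-based test with tie correction and the chi-square approximation
#' (df = groups - 1). When every observation is identical the statistic is
#' degenerate; the function returns p = 1 with a warning.
#'
#' @param groups Named list of numeric vectors, one per group (>= 2 groups,
#'   each non-empty).
#' @return List with `statistic` (H) and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1L)) == 0L)) stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) < 2L) {
    warning("all observations identical; Kruskal-Wallis p = 1")
    return(list(statistic = 0, p = 1))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1L))))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

# Two-sided rank-sum p: exact when combined n <= exact_max and tie-free,
# otherwise normal approximation with continuity and tie correction.
.rank_sum_p <- function(x, y, exact_max = 25L) {
  tie_free <- !anyDuplicated(c(x, y))
  use_exact <- (length(x) + length(y)) <= exact_max && tie_free
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
  # fully tied data degenerates the normal approximation (0/0); no evidence
  if (is.nan(p)) p <- 1
  p
}

#' Pairwise two-sided Wilcoxon rank-sum tests with BH correction
#'
#' Runs the requested pairwise comparisons and adjusts across that family
#' only. Exact p-values are used for tie-free data with combined n <= 25;
#' larger or tied comparisons use the normal approximation with continuity
#' and tie correction (the switch is recorded per comparison).
#'
#' @param groups Named list of numeric vectors.
#' @param comparisons List of length-2 character vectors of group names;
#'   default all pairs.
#' @return Data frame `group_i`, `group_j`, `n_i`, `n_j`, `exact`, `raw_p`,
#'   `adj_p`.
#' @export
pairwise_wilcoxon_bh <- function(groups, comparisons = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (is.null(comparisons)) {
    nm <- names(groups)
    comparisons <- utils::combn(nm, 2L, simplify = FALSE)
  }
  rows <- lapply(comparisons, function(cmp) {
    if (!all(cmp %in% names(groups))) {
      stop("comparison refers to unknown group: ", paste(cmp, collapse = " vs "))
    }
    x <- groups[[cmp[[1L]]]]; y <- groups[[cmp[[2L]]]]
    if (length(x) == 0L || length(y) == 0L) stop("empty group in comparison")
    tie_free <- !anyDuplicated(c(x, y))
    data.frame(group_i = cmp[[1L]], group_j = cmp[[2L]],
               n_i = length(x), n_j = length(y),
               exact = (length(x) + length(y)) <= 25L && tie_free,
               raw_p = .rank_sum_p(x, y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$raw_p)
  rownames(out) <- NULL
  out
}

#' Omnibus-gated group comparison
#'
#' The statistical recipe applied to every phenotype and composition panel:
#' Kruskal-Wallis across all groups first; pairwise Wilcoxon with BH only
#' when the omnibus p passes the gate (default .05).
#'
#' @param groups Named list of numeric vectors.
#' @param comparisons Pairs to test when gated in; default all pairs.
#' @param gate_p Omnibus threshold below which pairwise tests run.
#' @param metric_name Label carried into the result.
#' @return A `group_comparison` list: `metric_name`, `sizes`, `medians`,
#'   `kw_statistic`, `kw_p`, `pairwise` (data frame, or NULL when gated out).
#' @export
compare_groups <- function(groups, comparisons = NULL, gate_p = 0.05,
                           metric_name = "metric") {
  kw <- kruskal_wallis(groups)
  pw <- NULL
  if (kw$p < gate_p) pw <- pairwise_wilcoxon_bh(groups, comparisons)
  structure(list(
    metric_name = metric_name,
    sizes = vapply(groups, length, integer(1L)),
    medians = vapply(groups, stats::median, numeric(1L)),
    kw_statistic = kw$statistic,
    kw_p = kw$p,
    pairwise = pw
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group comparison of", x$metric_name, "\n")
  cat("  groups:", paste(sprintf("%s (n=%d, median=%.4g)", names(x$sizes),
                                 x$sizes, x$medians), collapse = ", "), "\n")
  cat(sprintf("  Kruskal-Wallis H = %.4g, p = %.4g\n", x$kw_statistic, x$kw_p))
  if (is.null(x$pairwise)) {
    cat("  pairwise tests not run (omnibus gate)\n")
  } else {
    print(x$pairwise)
  }
  invisible(x)
}

#' Compare a composition metric across gene sets
#'
#' Joins each gene set to the per-gene composition table for one region kind
#' and runs the gated Kruskal-Wallis / pairwise-Wilcoxon recipe on the chosen
#' metric. Genes of a set without that region are dropped (a message gives
#' the count per set).
#'
#' @param profiles Composition table from [composition_table()].
#' @param sets List of [gene_set] objects; their names label the groups.
#' @param metric One of `"a_freq"`, `"length"`, `"motif_per_kb"`.
#' @param region_kind One of `"utr5"`, `"cds"`, `"utr3"`.
#' @param gate_p Omnibus gate; default .05.
#' @return A `group_comparison` (see [compare_groups()]).
#' @export
compare_metric_across_sets <- function(profiles, sets,
                                       metric = c("a_freq", "length", "motif_per_kb"),
                                       region_kind = c("cds", "utr5", "utr3"),
                                       gate_p = 0.05) {
  metric <- match.arg(metric)
  region_kind <- match.arg(region_kind)
  stopifnot(is.data.frame(profiles), is.list(sets))
  reg <- profiles[profiles$region_kind == region_kind, , drop = FALSE]
  groups <- lapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    vals <- reg[[metric]][match(s$genes, reg$gene_id)]
    n_drop <- sum(is.na(vals))
    if (n_drop > 0L) {
      message("set '", s$name, "': ", n_drop, " gene(s) without a ",
              region_kind, " region dropped")
    }
    vals[!is.na(vals)]
  })
  names(groups) <- vapply(sets, function(s) s$name, character(1L))
  empty <- names(groups)[vapply(groups, length, integer(1L)) == 0L]
  if (length(empty) > 0L) {
    stop("gene set(s) with no usable rows for ", metric, "/", region_kind,
         ": ", paste(empty, collapse = ", "))
  }
  compare_groups(groups, gate_p = gate_p,
                 metric_name = paste(metric, region_kind, sep = "_"))
}

#' Phenotype comparison against a reference group
#'
#' Recomputation hook for per-plant phenotype tables: optionally applies the
#' bolting filter (keep plants with floral stem mass > 100 mg and at least
#' one flower, when those columns are present), then runs the gated
#' Kruskal-Wallis / Wilcoxon-BH recipe comparing every group against the
#' reference, and reports each group's percent change in mean relative to
#' the reference.
#'
#' @param phenotype Data frame with a group column and numeric trait columns.
#' @param trait Name of the trait column to compare.
#' @param group_col Name of the group column; default `"group"`.
#' @param reference Reference group label (e.g. the wild type).
#' @param bolting_filter Apply the bolting row filter when the columns
#'   `floral_stem_mass_mg` and `flowers` exist; default TRUE.
#' @param gate_p Omnibus gate; default .05.
#' @return A `group_comparison` with an extra element `pct_change_vs_ref`
#'   (named numeric, percent change of group means vs the reference).
#' @export
phenotype_compare <- function(phenotype, trait, group_col = "group",
                              reference, bolting_filter = TRUE, gate_p = 0.05) {
  stopifnot(is.data.frame(phenotype), trait %in% names(phenotype),
            group_col %in% names(phenotype))
  if (bolting_filter &&
      all(c("floral_stem_mass_mg", "flowers") %in% names(phenotype))) {
    keep <- phenotype$floral_stem_mass_mg > 100 & phenotype$flowers >= 1
    message("bolting filter: ", sum(!keep), " plant(s) removed")
    phenotype <- phenotype[keep, , drop = FALSE]
  }
  labels <- unique(as.character(phenotype[[group_col]]))
  if (!reference %in% labels) stop("reference group '", reference, "' not found")
  groups <- split(phenotype[[trait]], as.character(phenotype[[group_col]]))
  groups <- groups[c(reference, setdiff(labels, reference))]
  comparisons <- lapply(setdiff(names(groups), reference),
                        function(g) c(reference, g))
  res <- compare_groups(groups, comparisons = comparisons, gate_p = gate_p,
                        metric_name = trait)
  mean_ref <- mean(groups[[reference]])
  others <- setdiff(names(groups), reference)
  res$pct_change_vs_ref <- vapply(
    others, function(g) 100 * (mean(groups[[g]]) - mean_ref) / mean_ref,
    numeric(1L))
  res
}
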
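#' Construct a gene set
#'
#' A named set of gene IDs plus a construction record (direction and how it
#' was built), the unit that flows through enrichment and composition
#' stratification.
#'
#' @param name Label for the set.
#' @param genes Character vector of gene IDs (duplicates removed).
#' @param direction One of `"up"`, `"down"`, `"random"`, `"custom"`.
#' @param provenance Free-form list recording how the set was built.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, genes, direction = c("custom", "up", "down", "random"),
                     provenance = list()) {
  direction <- match.arg(direction)
  genes <- unique(as.character(genes))
  structure(list(name = name, genes = genes, direction = direction,
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "' (", x$direction, "): ", length(x$genes),
      " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Top-n genes by log2 fold change
#'
#' Ranks a DE table by `log2fc` (descending for `"up"`, ascending for
#' `"down"`), breaking ties by ascending adjusted p then lexicographic gene
#' ID, and returns the first `n` genes. Rows with missing `log2fc` are
#' dropped. When all fold changes point the other way the least-opposed
#' genes are still returned (a message notes this).
#'
#' @param de A `de_table` data frame.
#' @param n Number of genes; default 100.
#' @param direction `"up"` or `"down"`.
#' @param name Optional set name.
#' @return A [gene_set] of `min(n, available)` genes.
#' @export
top_n_by_lfc <- function(de, n = 100L, direction = c("up", "down"), name = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(de), all(c("gene_id", "log2fc") %in% names(de)), n >= 1L)
  de <- de[!is.na(de$log2fc), , drop = FALSE]
  if (nrow(de) == 0L) stop("DE table has no genes with a fold change")
  padj <- if ("p_adj" %in% names(de)) de$p_adj else rep(NA_real_, nrow(de))
  padj[is.na(padj)] <- Inf
  key <- if (direction == "up") -de$log2fc else de$log2fc
  ord <- order(key, padj, de$gene_id)
  picked <- de$gene_id[ord][seq_len(min(n, nrow(de)))]
  if ((direction == "up" && max(de$log2fc) <= 0) ||
      (direction == "down" && min(de$log2fc) >= 0)) {
    message("no ", direction, "-direction fold changes; returning the ",
            length(picked), " least-opposed genes")
  }
  gene_set(name %||% paste0("top", n, "_", direction), picked,
           direction = direction,
           provenance = list(policy = "top_n_by_lfc", n = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine per-line gene sets under a sharing policy
#'
#' The `"all_or_subset"` policy takes the union of the intersection of all
#' sets and the intersection of a named subset of them — the rule used when
#' one line is weaker than the others. When the subset is contained in the
#' full collection this reduces to the plain intersection of the subset, and
#' that reduction is recorded in the provenance. The `"k_of_n"` policy keeps
#' genes present in at least `k` sets.
#'
#' @param sets A list of [gene_set] objects (>= 2).
#' @param policy `"all_or_subset"` or `"k_of_n"`.
#' @param subset For `"all_or_subset"`: names (or indices) of the subset of
#'   sets whose intersection is also admitted.
#' @param k For `"k_of_n"`: minimum number of sets a gene must appear in.
#' @param name Optional name for the result.
#' @return A [gene_set].
#' @export
shared_set <- function(sets, policy = c("all_or_subset", "k_of_n"),
                       subset = NULL, k = NULL, name = NULL) {
  policy <- match.arg(policy)
  stopifnot(is.list(sets), length(sets) >= 2L,
            all(vapply(sets, inherits, logical(1L), "gene_set")))
  set_names <- vapply(sets, function(s) s$name, character(1L))
  gene_lists <- lapply(sets, function(s) s$genes)
  names(gene_lists) <- set_names
  if (policy == "all_or_subset") {
    if (is.null(subset)) stop("policy 'all_or_subset' needs 'subset'")
    if (is.numeric(subset)) subset <- set_names[subset]
    if (!all(subset %in% set_names)) stop("unknown set name(s) in 'subset'")
    inter_all <- Reduce(intersect, gene_lists)
    inter_sub <- Reduce(intersect, gene_lists[subset])
    genes <- union(inter_all, inter_sub)
    reduces <- all(set_names %in% set_names) && all(subset %in% set_names) &&
      length(setdiff(inter_all, inter_sub)) == 0L
    prov <- list(policy = "all_or_subset", sets = set_names, subset = subset,
                 reduces_to_subset_intersection = reduces)
  } else {
    if (is.null(k) || k < 1L || k > length(sets)) stop("'k' must be in 1..length(sets)")
    tab <- table(unlist(lapply(gene_lists, unique)))
    genes <- names(tab)[tab >= k]
    prov <- list(policy = "k_of_n", sets = set_names, k = k)
  }
  dirs <- unique(vapply(sets, function(s) s$direction, character(1L)))
  gene_set(name %||% paste0("shared_", paste(set_names, collapse = "+")),
           sort(genes),
           direction = if (length(dirs) == 1L) dirs else "custom",
           provenance = prov)
}

#' Hypergeometric overlap test for two gene sets
#'
#' Tests whether two sets drawn from a universe of `universe_size` genes
#' share more members than chance: the upper-tail probability of observing
#' at least the realized overlap under sampling without replacement.
#'
#' @param a,b [gene_set] objects.
#' @param universe_size Number of genes in the universe both sets were drawn
#'   from; must be at least each set's size.
#' @return An `overlap_test` list: `k_observed`, `n_a`, `n_b`,
#'   `universe_size`, `expected` (`n_a * n_b / M`), `p_upper`.
#' @export
overlap_test <- function(a, b, universe_size) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  n_a <- length(a$genes); n_b <- length(b$genes)
  if (n_a > universe_size || n_b > universe_size) {
    stop("set larger than the universe")
  }
  k <- length(intersect(a$genes, b$genes))
  p <- stats::phyper(k - 1L, n_a, universe_size - n_a, n_b, lower.tail = FALSE)
  structure(list(k_observed = k, n_a = n_a, n_b = n_b,
                 universe_size = universe_size,
                 expected = n_a * n_b / universe_size,
                 p_upper = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap %d (expected %.2f) of %d x %d in universe %d; P(X>=k) = %.4g\n",
              x$k_observed, x$expected, x$n_a, x$n_b, x$universe_size, x$p_upper))
  invisible(x)
}

#' Uniform random gene set
#'
#' Samples `n` genes without replacement from a universe, reproducibly under
#' a seed — the random reference stratum for composition comparisons.
#'
#' @param universe Character vector of gene IDs.
#' @param n Set size (<= length of universe).
#' @param seed Integer seed.
#' @param name Optional set name.
#' @return A [gene_set] with direction `"random"`.
#' @export
random_gene_set <- function(universe, n, seed, name = NULL) {
  universe <- unique(as.character(universe))
  if (n > length(universe)) {
    stop("cannot sample ", n, " genes from a universe of ", length(universe))
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  genes <- sample(universe, n)
  gene_set(name %||% paste0("random", n), genes, direction = "random",
           provenance = list(policy = "uniform_without_replacement",
                             n = n, seed = seed))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Balanced up / down / random lists from an external DE table
#'
#' The re-analysis policy for published datasets: sort a DE table by fold
#' change and take the `n` most-upregulated, the `n` most-downregulated, and
#' `n` genes chosen uniformly at random from the whole table.
#'
#' @param de A DE table with `gene_id` and `log2fc` ([read_de_table()]).
#' @param n Size of each list; default 1000.
#' @param seed Seed for the random list.
#' @return Named list of three [gene_set]s: `up`, `down`, `random`.
#' @export
external_de_lists <- function(de, n = 1000L, seed = 1L) {
  list(
    up = top_n_by_lfc(de, n, "up", name = paste0("external_up", n)),
    down = top_n_by_lfc(de, n, "down", name = paste0("external_down", n)),
    random = random_gene_set(de$gene_id[!is.na(de$log2fc)], n, seed,
                             name = paste0("external_random", n))
  )
}
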
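#' Category fold-enrichment with a hypergeometric upper tail
#'
#' How over-represented is a category (e.g. SAUR, mitochondrial, plastid)
#' inside a gene set, relative to its frequency in the universe? Reports the
#' fold ratio `(k/n) / (K/M)` and the exact upper-tail probability of
#' drawing at least `k` category members in `n` draws without replacement.
#'
#' @param set A [gene_set].
#' @param category Character vector of category member gene IDs.
#' @param universe Character vector of all gene IDs under consideration.
#' @return An `enrichment_result` list: `set_name`, `k`, `n`, `K`, `M`,
#'   `fold`, `p_upper`.
#' @export
category_enrichment <- function(set, category, universe) {
  stopifnot(inherits(set, "gene_set"))
  universe <- unique(as.character(universe))
  category <- unique(as.character(category))
  if (length(set$genes) == 0L) stop("empty gene set")
  if (length(category) == 0L) stop("empty category")
  if (!all(set$genes %in% universe)) stop("gene set not contained in universe")
  if (!all(category %in% universe)) stop("category not contained in universe")
  n <- length(set$genes)
  K <- length(category)
  M <- length(universe)
  k <- length(intersect(set$genes, category))
  fold <- (k / n) / (K / M)
  p <- stats::phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
  structure(list(set_name = set$name, k = k, n = n, K = K, M = M,
                 fold = fold, p_upper = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("'%s': %d/%d in category (%d/%d in universe); fold = %.2f, P(X>=k) = %.3g\n",
              x$set_name, x$k, x$n, x$K, x$M, x$fold, x$p_upper))
  invisible(x)
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Conditional on the margins, sums the hypergeometric probabilities of all
#' tables no more probable than the observed one (within relative tolerance
#' 1e-7) — the conventional two-tailed rule. Tables with an empty row or
#' column margin are reported as p = 1 with a warning rather than an error,
#' since keyword screens can legitimately produce them.
#'
#' @param tab A 2x2 matrix of non-negative counts; rows are the two gene
#'   sets, columns in-category / not-in-category.
#' @return The two-tailed p-value.
#' @export
fisher_two_tailed <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("'tab' must be 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 margin; p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Keyword screen over GO term names
#'
#' Flags a gene when any of its annotation term names contains any keyword
#' (case-insensitive substring match), builds the 2x2 table of matched /
#' unmatched genes for two sets, and tests it with the two-tailed Fisher
#' exact test. Genes missing from the annotation count as unmatched (a
#' message reports how many).
#'
#' @param set_a,set_b [gene_set] objects to contrast (e.g. shared-up vs
#'   shared-down).
#' @param annotations Data frame `gene_id`, `label` ([read_annotation()]),
#'   one row per gene-term pair; labels are term names, not IDs.
#' @param keywords Character vector of keywords (>= 1).
#' @return A `screen_result` list: `table` (2x2, rows A/B, cols
#'   match/no-match), `p`, `matched_a`, `matched_b` (the matching gene IDs).
#' @export
keyword_screen <- function(set_a, set_b, annotations, keywords) {
  stopifnot(inherits(set_a, "gene_set"), inherits(set_b, "gene_set"))
  if (length(keywords) == 0L) stop("'keywords' must be non-empty")
  stopifnot(is.data.frame(annotations),
            all(c("gene_id", "label") %in% names(annotations)))
  matcher <- function(genes) {
    ann <- annotations[annotations$gene_id %in% genes, , drop = FALSE]
    n_missing <- sum(!genes %in% annotations$gene_id)
    if (n_missing > 0L) {
      message(n_missing, " gene(s) without annotation counted as no-keyword")
    }
    hit_rows <- rep(FALSE, nrow(ann))
    for (kw in keywords) {
      hit_rows <- hit_rows | grepl(kw, ann$label, ignore.case = TRUE, fixed = FALSE)
    }
    unique(ann$gene_id[hit_rows])
  }
  ma <- matcher(set_a$genes)
  mb <- matcher(set_b$genes)
  tab <- matrix(c(length(ma), length(set_a$genes) - length(ma),
                  length(mb), length(set_b$genes) - length(mb)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c(set_a$name, set_b$name), c("match", "no_match")))
  p <- fisher_two_tailed(tab)
  structure(list(table = tab, p = p, matched_a = ma, matched_b = mb,
                 keywords = keywords),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  print(x$table)
  cat("two-tailed Fisher p =", format(x$p, digits = 3), "\n")
  invisible(x)
}

#' Tissue of maximal expression per gene
#'
#' For each gene in an expression atlas, the tissue with the highest value;
#' ties are broken by lexicographic tissue name. Genes whose row is entirely
#' missing are unassigned (NA).
#'
#' @param atlas Numeric matrix, genes x tissues ([read_atlas()]).
#' @return Named character vector gene -> tissue (NA when unassignable).
#' @export
tissue_max_assignment <- function(atlas) {
  atlas <- as.matrix(atlas)
  if (ncol(atlas) < 1L) stop("atlas needs at least one tissue column")
  ord <- order(colnames(atlas))
  atlas <- atlas[, ord, drop = FALSE]
  assign_one <- function(row) {
    if (all(is.na(row))) return(NA_character_)
    colnames(atlas)[which.max(row)]
  }
  out <- apply(atlas, 1L, assign_one)
  stats::setNames(out, rownames(atlas))
}

#' Membership screen between two gene sets
#'
#' Generic 2x2 screen: given a predicate set of genes (e.g. genes whose
#' tissue of maximal expression is senescent), counts members and
#' non-members in each of two gene sets and applies the two-tailed Fisher
#' exact test. [keyword_screen()] is the special case where the predicate
#' comes from term-name matching.
#'
#' @param set_a,set_b [gene_set] objects.
#' @param members Character vector of genes satisfying the predicate.
#' @return A `screen_result` (see [keyword_screen()]).
#' @export
membership_screen <- function(set_a, set_b, members) {
  stopifnot(inherits(set_a, "gene_set"), inherits(set_b, "gene_set"))
  members <- unique(as.character(members))
  ma <- intersect(set_a$genes, members)
  mb <- intersect(set_b$genes, members)
  tab <- matrix(c(length(ma), length(set_a$genes) - length(ma),
                  length(mb), length(set_b$genes) - length(mb)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c(set_a$name, set_b$name), c("match", "no_match")))
  structure(list(table = tab, p = fisher_two_tailed(tab),
                 matched_a = ma, matched_b = mb, keywords = NULL),
            class = "screen_result")
}
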
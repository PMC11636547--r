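#' Degenerate motif patterns
#'
#' A motif pattern is an ordered list of allowed-base sets, one per position,
#' in the IUPAC sense. The m6A consensus RRACH (R = A/G, H = A/C/T on the
#' DNA-sense strand) is the motif this package exists to measure, but any
#' IUPAC string works.
#'
#' @param iupac A single IUPAC nucleotide string, e.g. `"RRACH"`. `U` is
#'   treated as `T` (sequences are handled DNA-sense throughout).
#' @return An object of class `motif_pattern`: a list with elements
#'   `label` (the input string) and `positions` (a list of character vectors,
#'   each a non-empty subset of A/C/G/T).
#' @examples
#' motif_pattern("RRACH")
#' @export
motif_pattern <- function(iupac) {
  if (!is.character(iupac) || length(iupac) != 1L || is.na(iupac) || !nzchar(iupac)) {
    stop("'iupac' must be a single non-empty string")
  }
  iupac <- chartr("u", "t", iupac)
  iupac <- toupper(chartr("U", "T", iupac))
  letters <- strsplit(iupac, "", fixed = TRUE)[[1L]]
  code_map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(letters, names(code_map))
  if (length(bad) > 0L) {
    stop("unknown IUPAC letter(s): ", paste(unique(bad), collapse = ", "))
  }
  positions <- lapply(letters, function(l) {
    strsplit(code_map[[l]], "", fixed = TRUE)[[1L]]
  })
  structure(list(label = iupac, positions = positions), class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  sets <- vapply(x$positions, function(p) paste0("{", paste(p, collapse = ","), "}"),
                 character(1L))
  cat("motif_pattern ", x$label, ": ", paste(sets, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
length.motif_pattern <- function(x) length(x$positions)

as_motif <- function(motif) {
  if (inherits(motif, "motif_pattern")) return(motif)
  if (is.character(motif) && length(motif) == 1L) return(motif_pattern(motif))
  stop("'motif' must be a motif_pattern or a single IUPAC string")
}

# Split to uppercase character vector, RNA U mapped to T.
.seq_chars <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  strsplit(toupper(chartr("Uu", "Tt", seq)), "", fixed = TRUE)[[1L]]
}

#' Base frequency in a nucleotide sequence
#'
#' Fraction of unambiguous (A/C/G/T) positions carrying `base`. Ambiguous
#' letters such as N are excluded from the denominator, so the result is a
#' composition estimate rather than a per-physical-base rate.
#'
#' @param seq A single nucleotide string (case-insensitive; U read as T).
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return A fraction in \[0, 1\], or `NA_real_` if the sequence has no
#'   unambiguous positions (including the empty sequence).
#' @examples
#' base_frequency("ACGT", "A")   # 0.25
#' base_frequency("ACGTN", "A")  # 0.25; N not in the denominator
#' @export
base_frequency <- function(seq, base = "A") {
  base <- toupper(base)
  if (!base %in% c("A", "C", "G", "T")) stop("'base' must be one of A, C, G, T")
  chars <- .seq_chars(seq)
  n_valid <- sum(chars %in% c("A", "C", "G", "T"))
  if (n_valid == 0L) return(NA_real_)
  sum(chars == base) / n_valid
}

#' Count degenerate motif occurrences
#'
#' Slides a window of the motif's length along the sequence and counts every
#' position-wise match; overlapping occurrences are all counted. A window
#' containing any letter outside A/C/G/T never matches.
#'
#' @inheritParams base_frequency
#' @param motif A [motif_pattern] or IUPAC string.
#' @return Non-negative integer count.
#' @examples
#' motif_count("GGACAGACT", "RRACH")  # 2, at offsets 1 and 5
#' @export
motif_count <- function(seq, motif = "RRACH") {
  motif <- as_motif(motif)
  chars <- .seq_chars(seq)
  k <- length(motif$positions)
  n <- length(chars)
  if (n < k) return(0L)
  hit <- chars %in% motif$positions[[1L]]
  hit <- hit[seq_len(n - k + 1L)]
  if (k > 1L) {
    for (i in 2L:k) {
      hit <- hit & (chars %in% motif$positions[[i]])[i:(n - k + i)]
    }
  }
  sum(hit)
}

#' Motif density per kilobase
#'
#' `1000 * motif_count / nchar(seq)`. The denominator is the physical length
#' in bases, ambiguous letters included (contrast [base_frequency]).
#'
#' @inheritParams motif_count
#' @return Density in motifs per kb; `NA_real_` for an empty sequence.
#' @examples
#' motif_density_per_kb("GGACAGACT", "RRACH")  # 2000/9
#' @export
motif_density_per_kb <- function(seq, motif = "RRACH") {
  stopifnot(is.character(seq), length(seq) == 1L)
  len <- nchar(seq)
  if (len == 0L) return(NA_real_)
  1000 * motif_count(seq, motif) / len
}

#' Analytic expected motif density under an i.i.d. base model
#'
#' Expected sliding-window matches per kb when bases are drawn independently
#' with probabilities `base_probs`: 1000 times the product over motif
#' positions of the summed probabilities of the allowed bases. End effects
#' are ignored. Under equal base frequencies the RRACH expectation is
#' `1000 * (1/2)(1/2)(1/4)(1/4)(3/4) = 11.71875`, i.e. about 12 per kb.
#'
#' @inheritParams motif_count
#' @param base_probs Named numeric over A/C/G/T, non-negative, summing to 1.
#' @return Expected motifs per kb.
#' @examples
#' expected_motif_density("RRACH")  # 11.71875
#' @export
expected_motif_density <- function(motif = "RRACH",
                                   base_probs = c(A = .25, C = .25, G = .25, T = .25)) {
  motif <- as_motif(motif)
  if (is.null(names(base_probs)) || !setequal(names(base_probs), c("A", "C", "G", "T"))) {
    stop("'base_probs' must be named over exactly A, C, G, T")
  }
  if (any(base_probs < 0)) stop("'base_probs' must be non-negative")
  if (abs(sum(base_probs) - 1) > 1e-9) stop("'base_probs' must sum to 1")
  1000 * prod(vapply(motif$positions, function(p) sum(base_probs[p]), numeric(1L)))
}

#' Per-gene, per-region composition table
#'
#' Computes, for every gene and each of the 5'UTR / CDS / 3'UTR regions that
#' is non-empty, the metrics the stratification analysis compares across
#' up/down/random gene sets: length, adenosine frequency, motif count and
#' motif density per kb. Two lengths are reported: `length` (all bases) and
#' `length_acgt` (unambiguous bases only), so density can be renormalized
#' either way.
#'
#' @param regions A `transcript_regions` data frame as returned by
#'   [extract_regions()] or [simulate_genome()] (columns `gene_id`,
#'   `utr5_seq`, `cds_seq`, `utr3_seq`).
#' @param motif A [motif_pattern] or IUPAC string; default the m6A consensus
#'   RRACH.
#' @return A data frame with columns `gene_id`, `region_kind` (utr5/cds/utr3),
#'   `length`, `length_acgt`, `a_freq`, `motif_count`, `motif_per_kb`. Genes
#'   with an empty region contribute no row for that kind.
#' @export
composition_table <- function(regions, motif = "RRACH") {
  motif <- as_motif(motif)
  stopifnot(is.data.frame(regions),
            all(c("gene_id", "utr5_seq", "cds_seq", "utr3_seq") %in% names(regions)))
  kinds <- c(utr5 = "utr5_seq", cds = "cds_seq", utr3 = "utr3_seq")
  out <- lapply(names(kinds), function(kind) {
    seqs <- regions[[kinds[[kind]]]]
    keep <- !is.na(seqs) & nzchar(seqs)
    if (!any(keep)) return(NULL)
    seqs <- seqs[keep]
    counts <- vapply(seqs, motif_count, integer(1L), motif = motif, USE.NAMES = FALSE)
    lens <- nchar(seqs)
    chars <- strsplit(toupper(chartr("Uu", "Tt", seqs)), "", fixed = TRUE)
    n_acgt <- vapply(chars, function(x) sum(x %in% c("A", "C", "G", "T")), integer(1L))
    n_a <- vapply(chars, function(x) sum(x == "A"), integer(1L))
    data.frame(
      gene_id = regions$gene_id[keep],
      region_kind = kind,
      length = lens,
      length_acgt = n_acgt,
      a_freq = ifelse(n_acgt > 0L, n_a / n_acgt, NA_real_),
      motif_count = counts,
      motif_per_kb = 1000 * counts / lens,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), region_kind = character(),
                      length = integer(), length_acgt = integer(),
                      a_freq = numeric(), motif_count = integer(),
                      motif_per_kb = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
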
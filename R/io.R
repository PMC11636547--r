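#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`; other IUPAC letters
#' are preserved. Record order follows the file. Sequence IDs are the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ID(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(chartr("Uu", "Tt", as.character(set)))
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA wrapped at 60 columns
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA`, `five_prime_UTR`, `CDS` and `three_prime_UTR`
#' features and returns one model per gene built from one of its mRNAs.
#' Coordinates are kept 1-based inclusive (the GFF3 and GRanges convention).
#'
#' @param path Path to a GFF3 file.
#' @param isoform_policy `"first"` (default) keeps each gene's first-listed
#'   mRNA; `"longest_cds"` keeps the mRNA with the largest summed CDS length.
#'   A message notes genes where the choice mattered.
#' @return A `gene_models` data frame: one row per region segment, columns
#'   `gene_id`, `seq_id`, `strand` (`+`/`-`), `kind` (utr5/cds/utr3),
#'   `start`, `end` (1-based inclusive). Segments of one kind are
#'   non-overlapping; they are stored in ascending genomic order and
#'   reoriented at extraction time.
#' @export
read_gff3 <- function(path, isoform_policy = c("first", "longest_cds")) {
  isoform_policy <- match.arg(isoform_policy)
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$ID <- as.character(df$ID)
  parent <- vapply(as.list(df$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1L))
  df$parent <- parent
  df$order <- seq_len(nrow(df))

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  kind_map <- c(five_prime_UTR = "utr5", CDS = "cds", three_prime_UTR = "utr3")
  feats <- df[df$type %in% names(kind_map), , drop = FALSE]
  if (nrow(feats) == 0L) stop("no CDS/UTR features in ", path)

  orphan <- !(feats$parent %in% mrnas$ID)
  if (any(orphan)) {
    stop("feature(s) without an mRNA parent that belongs to a gene: ",
         paste(utils::head(feats$ID[orphan], 5L), collapse = ", "))
  }
  mrna_gene <- stats::setNames(mrnas$parent, mrnas$ID)
  if (any(!(mrnas$parent %in% genes$ID))) stop("mRNA without parent gene in ", path)

  # pick one mRNA per gene
  chosen <- vapply(genes$ID, function(g) {
    cand <- mrnas[mrnas$parent == g, , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_character_)
    if (nrow(cand) > 1L) {
      if (isoform_policy == "longest_cds") {
        cds_len <- vapply(cand$ID, function(m) {
          f <- feats[feats$parent == m & feats$type == "CDS", , drop = FALSE]
          sum(f$end - f$start + 1L)
        }, numeric(1L))
        pick <- cand$ID[which.max(cds_len)]
      } else {
        pick <- cand$ID[which.min(cand$order)]
      }
      message("gene ", g, " has ", nrow(cand), " mRNAs; using ", pick,
              " (policy: ", isoform_policy, ")")
      return(pick)
    }
    cand$ID[1L]
  }, character(1L))
  chosen <- chosen[!is.na(chosen)]
  if (length(chosen) == 0L) stop("no gene with an mRNA found in ", path)

  keep <- feats[feats$parent %in% chosen, , drop = FALSE]
  models <- data.frame(
    gene_id = unname(mrna_gene[keep$parent]),
    seq_id = as.character(keep$seqnames),
    strand = as.character(keep$strand),
    kind = unname(kind_map[keep$type]),
    start = keep$start,
    end = keep$end,
    stringsAsFactors = FALSE
  )
  if (any(!models$strand %in% c("+", "-"))) {
    stop("gene model(s) with undefined strand in ", path)
  }
  models <- models[order(models$gene_id, models$start), , drop = FALSE]
  rownames(models) <- NULL
  class(models) <- c("gene_models", "data.frame")
  models
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA / five_prime_UTR / CDS / three_prime_UTR features with
#' `ID` and `Parent` attributes, 1-based inclusive coordinates, in
#' deterministic order (genes sorted by start).
#'
#' @param models A `gene_models` data frame (see [read_gff3()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  stopifnot(is.data.frame(models),
            all(c("gene_id", "seq_id", "strand", "kind", "start", "end") %in% names(models)))
  type_map <- c(utr5 = "five_prime_UTR", cds = "CDS", utr3 = "three_prime_UTR")
  lines <- c("##gff-version 3")
  gene_start <- tapply(models$start, models$gene_id, min)
  gene_ids <- names(sort(gene_start))
  for (g in gene_ids) {
    seg <- models[models$gene_id == g, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    chrom <- seg$seq_id[1L]
    strand <- seg$strand[1L]
    gs <- min(seg$start); ge <- max(seg$end)
    mid <- paste0(g, ".1")
    lines <- c(lines,
      paste(chrom, "rrachstrat", "gene", gs, ge, ".", strand, ".",
            paste0("ID=", g), sep = "\t"),
      paste(chrom, "rrachstrat", "mRNA", gs, ge, ".", strand, ".",
            paste0("ID=", mid, ";Parent=", g), sep = "\t"))
    for (i in seq_len(nrow(seg))) {
      phase <- if (seg$kind[i] == "cds") "0" else "."
      lines <- c(lines,
        paste(chrom, "rrachstrat", type_map[[seg$kind[i]]],
              seg$start[i], seg$end[i], ".", strand, phase,
              paste0("ID=", mid, ".", seg$kind[i], i, ";Parent=", mid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.revcomp <- function(seq) {
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract 5'UTR / CDS / 3'UTR sequences for each gene model
#'
#' Segments of one kind are concatenated in transcript (5' to 3') order;
#' minus-strand genes are reverse-complemented so all returned sequences are
#' mRNA-sense. A missing region kind yields an empty string.
#'
#' @param models A `gene_models` data frame ([read_gff3()]).
#' @param genome Named character vector of contig sequences ([read_fasta()]).
#' @return A `transcript_regions` data frame: `gene_id`, `utr5_seq`,
#'   `cds_seq`, `utr3_seq`, and `cds_complete` (`TRUE` when the CDS length is
#'   a multiple of 3 and non-empty).
#' @export
extract_regions <- function(models, genome) {
  stopifnot(is.data.frame(models), is.character(genome), !is.null(names(genome)))
  missing_contig <- setdiff(unique(models$seq_id), names(genome))
  if (length(missing_contig) > 0L) {
    stop("contig(s) absent from genome: ", paste(missing_contig, collapse = ", "))
  }
  contig_len <- nchar(genome)
  bad <- models$start < 1L | models$end > contig_len[models$seq_id] |
    models$end < models$start
  if (any(bad)) {
    stop("coordinates beyond contig for gene(s): ",
         paste(utils::head(unique(models$gene_id[bad]), 5L), collapse = ", "))
  }
  models <- models[order(models$gene_id, models$start), , drop = FALSE]
  pieces <- substring(genome[models$seq_id], models$start, models$end)
  key <- paste(models$gene_id, models$kind, sep = "\r")
  # segments are in ascending genomic order within each key
  joined <- vapply(split(pieces, key)[unique(key)], paste, character(1L),
                   collapse = "")
  strand_of <- models$strand[!duplicated(models$gene_id)]
  names(strand_of) <- models$gene_id[!duplicated(models$gene_id)]
  gene_ids <- names(strand_of)

  get_kind <- function(kind) {
    s <- joined[paste(gene_ids, kind, sep = "\r")]
    s[is.na(s)] <- ""
    names(s) <- gene_ids
    flip <- strand_of == "-" & nzchar(s)
    if (any(flip)) {
      s[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s[flip])))
    }
    s
  }
  utr5 <- get_kind("utr5"); cds <- get_kind("cds"); utr3 <- get_kind("utr3")
  res <- data.frame(gene_id = gene_ids, utr5_seq = unname(utr5),
                    cds_seq = unname(cds), utr3_seq = unname(utr3),
                    cds_complete = nzchar(cds) & nchar(cds) %% 3L == 0L,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("transcript_regions", "data.frame")
  res
}

#' Read a counts matrix from TSV
#'
#' First column is the gene ID; remaining columns are samples.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix, genes in rows (rownames), samples in columns.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts table needs a gene column plus >=1 sample: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  if (any(m < 0)) stop("negative counts in ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a counts matrix as TSV
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an externally produced differential-expression table
#'
#' Expects at least `gene_id` and `log2fc`; `p_raw` and `p_adj` are carried
#' through when present (absent columns become NA). Used to re-analyze
#' published datasets where only the DE summary is available.
#'
#' @param path Path to a TSV with a header.
#' @return A `de_table`-compatible data frame.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc")
  if (!all(need %in% names(df))) {
    stop("DE table ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  for (col in c("p_raw", "p_adj")) if (!col %in% names(df)) df[[col]] <- NA_real_
  df
}

#' Write any stage table as TSV
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene annotation table (gene -> label)
#'
#' Generic reader for gene-to-GO-term-name, gene-to-category and similar
#' long-format tables: first column gene ID, second the label; extra columns
#' ignored. A gene may appear on many rows.
#'
#' @param path Path to a TSV with a header.
#' @return Data frame with columns `gene_id`, `label`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation table needs >=2 columns: ", path)
  out <- data.frame(gene_id = as.character(df[[1L]]), label = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  out
}

#' Read a gene x tissue expression atlas from TSV
#' @param path Path to a TSV; first column gene IDs, remaining tissues.
#' @return Numeric matrix with gene rownames and tissue colnames.
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("atlas needs a gene column plus >=1 tissue: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}
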
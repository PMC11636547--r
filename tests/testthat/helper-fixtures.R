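# In-code fixtures shared across test files.

write_tiny_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  }))
  writeLines(lines, path)
  path
}

# A two-gene GFF3: gA plus-strand with utr5/cds/utr3, gB minus-strand CDS-only.
write_tiny_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t5\t40\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t5\t40\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\ttest\tfive_prime_UTR\t5\t10\t.\t+\t.\tID=gA.1.u5;Parent=gA.1",
    "chr1\ttest\tCDS\t11\t16\t.\t+\t0\tID=gA.1.c;Parent=gA.1",
    "chr1\ttest\tthree_prime_UTR\t17\t40\t.\t+\t.\tID=gA.1.u3;Parent=gA.1",
    "chr1\ttest\tgene\t51\t56\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t51\t56\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\ttest\tCDS\t51\t56\t.\t-\t0\tID=gB.1.c;Parent=gB.1"
  ), path)
  path
}

# Minimal DE table for list-building tests.
make_de_table <- function(gene_id, log2fc, p_adj = NULL, p_raw = NULL) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id, log2fc = log2fc,
             p_raw = p_raw %||% rep(NA_real_, n),
             p_adj = p_adj %||% rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Annotation table giving n_match genes of a set a term containing `word`.
make_keyword_annotation <- function(set_a, set_b, n_match_a, n_match_b,
                                    word = "fungus") {
  genes <- c(set_a$genes, set_b$genes)
  labels <- rep("housekeeping process", length(genes))
  hit <- c(head(set_a$genes, n_match_a), head(set_b$genes, n_match_b))
  labels[genes %in% hit] <- paste("defense response to", word)
  data.frame(gene_id = genes, label = labels, stringsAsFactors = FALSE)
}
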
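test_that("FASTA reading uppercases, maps U to T and preserves order", {
  p <- write_tiny_fasta(list(x = "acgt", y = "uuagg"))
  got <- read_fasta(p)
  expect_identical(got, c(x = "ACGT", y = "TTAGG"))
})

test_that("wrapped FASTA records are concatenated and round-trip at 60 cols", {
  seq <- paste(rep("ACGTA", 30), collapse = "")  # 150 bases
  p <- tempfile(fileext = ".fa")
  write_fasta(c(long = seq), p)
  lines <- readLines(p)
  expect_equal(nchar(lines[2:3]), c(60L, 60L))
  expect_identical(read_fasta(p)[["long"]], seq)
})

test_that("FASTA errors: duplicate IDs and empty files", {
  p <- write_tiny_fasta(list(x = "ACGT"))
  dup <- tempfile(fileext = ".fa")
  writeLines(c(">x", "AC", ">x", "GT"), dup)
  expect_error(read_fasta(dup), "duplicate")
  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_fasta(empty), "empty")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("GFF3 coordinates stay 1-based inclusive through extraction", {
  #           1234567890123456
  contig <- "AAAAAAAAAAGGACATTTTTTTTTTTTTTTTTTTTTTTTTGGACATACGT"
  contig <- paste0(contig, paste(rep("A", 60 - nchar(contig)), collapse = ""))
  genome <- c(chr1 = contig)
  models <- read_gff3(write_tiny_gff3())
  expect_s3_class(models, "gene_models")
  cds_a <- models[models$gene_id == "gA" & models$kind == "cds", ]
  expect_equal(cds_a$end - cds_a$start + 1L, 6L)
  regions <- extract_regions(models, genome)
  a <- regions[regions$gene_id == "gA", ]
  # disk CDS 11..16 is the 6-mer starting at base 11
  expect_equal(a$cds_seq, "GGACAT")
  expect_equal(a$utr5_seq, substr(contig, 5, 10))
  expect_true(a$cds_complete)
})

test_that("minus-strand regions come back reverse-complemented, mRNA-sense", {
  contig <- paste0(strrep("A", 50), "GGACAT", strrep("A", 10))
  models <- read_gff3(write_tiny_gff3())
  regions <- extract_regions(models, c(chr1 = contig))
  b <- regions[regions$gene_id == "gB", ]
  # plus-sense GGACAT at 51..56, minus strand => ATGTCC
  expect_equal(b$cds_seq, "ATGTCC")
  expect_equal(b$utr5_seq, "")  # no annotated UTR -> empty string
  expect_equal(b$utr3_seq, "")
})

test_that("multiple mRNAs follow the stated isoform policy", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t30\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t30\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tt\tCDS\t1\t6\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\tt\tmRNA\t1\t30\t.\t+\t.\tID=m2;Parent=g1",
    "chr1\tt\tCDS\t1\t12\t.\t+\t0\tID=c2;Parent=m2"
  ), p)
  expect_message(first <- read_gff3(p), "using m1")
  expect_equal(sum(first$kind == "cds" & first$end == 6), 1L)
  expect_message(longest <- read_gff3(p, isoform_policy = "longest_cds"),
                 "using m2")
  expect_equal(sum(longest$kind == "cds" & longest$end == 12), 1L)
})

test_that("GFF3 structural errors are rejected", {
  orphan <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t30\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t30\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tt\tCDS\t1\t6\t.\t+\t0\tID=c1;Parent=ghost"
  ), orphan)
  expect_error(read_gff3(orphan), "without an mRNA parent")
  expect_error(read_gff3(tempfile()), "not found")
})

test_that("extraction errors name the offending gene or contig", {
  models <- read_gff3(write_tiny_gff3())
  expect_error(extract_regions(models, c(other = "ACGT")), "chr1")
  expect_error(extract_regions(models, c(chr1 = "ACGTACGT")), "gA")
})

test_that("simulated genomes survive the full write/read/extract round trip", {
  spec <- synthetic_spec(n_genes = 30, seed = 9)
  sim <- simulate_genome(spec)
  expect_setequal(unique(sim$models$strand), c("+", "-"))
  outdir <- tempfile()
  paths <- write_simulation(sim, NULL, outdir)
  genome <- read_fasta(paths[["fasta"]])
  models <- read_gff3(paths[["gff3"]])
  regions <- extract_regions(models, genome)
  regions <- regions[match(sim$regions$gene_id, regions$gene_id), ]
  rownames(regions) <- NULL
  expect_identical(regions$utr5_seq, sim$regions$utr5_seq)
  expect_identical(regions$cds_seq, sim$regions$cds_seq)
  expect_identical(regions$utr3_seq, sim$regions$utr3_seq)
})

test_that("reversing the genome and flipping strands leaves mRNA sequences fixed", {
  spec <- synthetic_spec(n_genes = 20, seed = 13)
  sim <- simulate_genome(spec)
  L <- nchar(sim$genome[["chr1"]])
  flipped_genome <- c(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sim$genome[["chr1"]]))))
  m <- sim$models
  new_start <- L - m$end + 1L
  new_end <- L - m$start + 1L
  m$start <- new_start
  m$end <- new_end
  m$strand <- ifelse(m$strand == "+", "-", "+")
  orig <- extract_regions(sim$models, sim$genome)
  flip <- extract_regions(m, flipped_genome)
  flip <- flip[match(orig$gene_id, flip$gene_id), ]
  rownames(flip) <- NULL
  expect_identical(flip$cds_seq, orig$cds_seq)
  expect_identical(flip$utr5_seq, orig$utr5_seq)
  expect_identical(flip$utr3_seq, orig$utr3_seq)
})

test_that("counts and table readers validate schemas", {
  cnt <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  p <- tempfile(fileext = ".tsv")
  write_counts(cnt, p)
  expect_identical(read_counts(p), cnt)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "g1\t-3"), bad)
  expect_error(read_counts(bad), "negative")
  de <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tfold", "g1\t2"), de)
  expect_error(read_de_table(de), "log2fc")
  ok <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc", "g1\t2"), ok)
  got <- read_de_table(ok)
  expect_true(all(c("p_raw", "p_adj") %in% names(got)))
})
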
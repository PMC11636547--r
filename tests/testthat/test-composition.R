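test_that("motif_pattern parses IUPAC strings and rejects malformed input", {
  m <- motif_pattern("RRACH")
  expect_s3_class(m, "motif_pattern")
  expect_length(m, 5L)
  expect_equal(m$positions, rrach_sets)
  # RNA-style spelling collapses to the DNA-sense pattern
  expect_equal(motif_pattern("rracu")$positions[[5L]], "T")
  expect_error(motif_pattern("RR@CH"), "IUPAC")
  expect_error(motif_pattern(""), "non-empty")
  expect_error(motif_pattern(c("A", "C")), "single")
})

test_that("base_frequency excludes ambiguous letters from the denominator", {
  expect_equal(base_frequency("AAAA", "A"), 1)
  expect_equal(base_frequency("ACGT", "A"), 0.25)
  expect_equal(base_frequency("ACGTN", "A"), 0.25)
  expect_equal(base_frequency("acgt", "A"), 0.25)
  expect_equal(base_frequency("UUUU", "T"), 1)
  expect_true(is.na(base_frequency("", "A")))
  expect_true(is.na(base_frequency("NNN", "A")))
  expect_error(base_frequency("ACGT", "N"), "must be one of")
})

test_that("motif_count matches hand enumeration on stated examples", {
  expect_equal(motif_count("AGACA", "RRACH"), 1L)
  # windows at offsets 1..5; only GGACA (1) and AGACT (5) match
  expect_equal(motif_count("GGACAGACT", "RRACH"), 2L)
  expect_equal(motif_count("GGNCT", "RRACH"), 0L)
  expect_equal(motif_count("GGAC", "RRACH"), 0L)
  expect_equal(motif_count("", "RRACH"), 0L)
})

test_that("motif_count agrees with a naive scanner and with Biostrings", {
  set.seed(11)
  for (i in 1:40) {
    len <- sample(0:200, 1)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
    got <- motif_count(seq, "RRACH")
    expect_identical(got, naive_motif_count(seq, rrach_sets))
    if (len >= 5) {
      bs <- Biostrings::countPattern("RRACH", Biostrings::DNAString(seq),
                                     fixed = "subject")
      expect_identical(got, bs)
    }
  }
})

test_that("motif density normalizes by physical length including ambiguity", {
  expect_equal(motif_density_per_kb("GGACAGACT", "RRACH"), 2000 / 9)
  one_kb <- paste(c(rep("GGACT", 12), rep("TTTTT", 188)), collapse = "")
  expect_equal(nchar(one_kb), 1000)
  expect_equal(motif_density_per_kb(one_kb, "RRACH"), 12)
  expect_true(is.na(motif_density_per_kb("", "RRACH")))
  expect_equal(motif_density_per_kb("ACG", "RRACH"), 0)
  # N counts in the length denominator but blocks matches
  expect_equal(motif_density_per_kb("GGACANNNNN", "RRACH"), 100)
})

test_that("analytic motif expectation matches closed-form products", {
  expect_equal(expected_motif_density("RRACH"), 11.71875)
  expect_equal(expected_motif_density("A"), 250)
  expect_equal(expected_motif_density("RRACH", c(A = .5, C = 0, G = .25, T = .25)), 0)
  set.seed(3)
  for (i in 1:10) {
    p <- runif(4); p <- p / sum(p); names(p) <- c("A", "C", "G", "T")
    manual <- 1000 * (p["A"] + p["G"])^2 * p["A"] * p["C"] * (p["A"] + p["C"] + p["T"])
    expect_equal(expected_motif_density("RRACH", p), unname(manual))
  }
  expect_error(expected_motif_density("RRACH", c(A = -1, C = 1, G = .5, T = .5)),
               "non-negative")
  expect_error(expected_motif_density("RRACH", c(A = .5, C = .5, G = .5, T = .5)),
               "sum to 1")
  expect_error(expected_motif_density("RRACH", c(x = 1, C = 0, G = 0, T = 0)),
               "named")
})

test_that("Monte-Carlo density of random sequences matches the expectation", {
  set.seed(29)
  seqs <- random_dna(200, 3000)
  dens <- vapply(seqs, motif_density_per_kb, numeric(1), motif = "RRACH",
                 USE.NAMES = FALSE)
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - 11.71875), 3 * se)
})

test_that("density is invariant under self-concatenation up to boundary term", {
  set.seed(17)
  for (len in c(60, 200, 1000)) {
    seq <- random_dna(1, len)
    d1 <- motif_density_per_kb(seq, "RRACH")
    d2 <- motif_density_per_kb(paste0(seq, seq), "RRACH")
    expect_lte(abs(d2 - d1), 1000 * 4 / (2 * len) + 1e-9)
  }
})

test_that("appending non-final-position letters never decreases the count", {
  set.seed(23)
  for (i in 1:20) {
    seq <- random_dna(1, 100)
    n0 <- motif_count(seq, "RRACH")
    # G is not in the final RRACH position set {A,C,T}
    n1 <- motif_count(paste0(seq, "GGGG"), "RRACH")
    expect_gte(n1, n0)
    expect_lte(n1, n0 + 1L)
  }
})

test_that("composition_table rows mirror the regions they were computed from", {
  regions <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    utr5_seq = c("ACGT", "", "TTT"),
    cds_seq = c(strrep("ACGT", 6), "GGACAGACT", ""),
    utr3_seq = c("GGACT", "NNNNA", ""),
    stringsAsFactors = FALSE
  )
  tab <- composition_table(regions, "RRACH")
  # one row per non-empty gene x region: g1 has 3, g2 has cds+utr3, g3 utr5
  expect_equal(nrow(tab), 6L)
  cds1 <- tab[tab$gene_id == "g1" & tab$region_kind == "cds", ]
  expect_equal(cds1$a_freq, 0.25)
  expect_equal(cds1$length, 24L)
  cds2 <- tab[tab$gene_id == "g2" & tab$region_kind == "cds", ]
  expect_equal(cds2$motif_count, 2L)
  expect_equal(cds2$motif_per_kb, 2000 / 9)
  u3 <- tab[tab$gene_id == "g2" & tab$region_kind == "utr3", ]
  expect_equal(u3$length, 5L)
  expect_equal(u3$length_acgt, 1L)
  expect_equal(u3$a_freq, 1)
  expect_false("g3" %in% tab$gene_id[tab$region_kind == "cds"])
})

test_that("composition_table reproduces the simulator truth table exactly", {
  spec <- synthetic_spec(n_genes = 60, seed = 5, rrach_boost = 10)
  sim <- simulate_genome(spec)
  tab <- composition_table(sim$regions, "RRACH")
  cds <- tab[tab$region_kind == "cds", ]
  cds <- cds[match(sim$truth$gene_id, cds$gene_id), ]
  expect_equal(cds$a_freq, sim$truth$a_freq_cds)
  expect_equal(cds$motif_per_kb, sim$truth$rrach_per_kb_cds)
  expect_equal(cds$length, sim$truth$cds_len)
})
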
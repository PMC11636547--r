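test_that("spec validation enforces the generator's invariants", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(n_genes = 0), ">= 1")
  expect_error(synthetic_spec(dispersion = 0), "> 0")
  expect_error(synthetic_spec(rrach_boost = -1), ">= 0")
  # 5-base motifs at > 200/kb cannot fit without overlap
  expect_error(synthetic_spec(rrach_boost = 201), "cannot fit")
  expect_error(
    synthetic_spec(compartment_probs = c(nuclear = .5, mito = .3, plastid = .3)),
    "sum to 1")
})

test_that("identical spec and seed reproduce byte-identical outputs", {
  spec <- synthetic_spec(n_genes = 40, seed = 77, rrach_boost = 5)
  sim1 <- simulate_genome(spec)
  sim2 <- simulate_genome(spec)
  expect_identical(sim1$genome, sim2$genome)
  expect_identical(sim1$truth, sim2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(sim1, simulate_counts(sim1$truth, spec), d1)
  write_simulation(sim2, simulate_counts(sim2$truth, spec), d2)
  for (f in c("genome.fa", "genes.gff3", "truth.tsv", "counts.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # the regions-only fast path draws the same gene sequences
  sim3 <- simulate_genome(spec, assemble = FALSE)
  expect_identical(sim3$regions, sim1$regions)
  expect_null(sim3$genome)
})

test_that("gene anatomy honours the transcript grammar", {
  spec <- synthetic_spec(n_genes = 80, seed = 19)
  sim <- simulate_genome(spec)
  truth <- sim$truth
  expect_true(all(truth$cds_len %% 3 == 0))
  expect_true(all(truth$a_freq_cds >= 0 & truth$a_freq_cds <= 1))
  expect_true(all(truth$rrach_per_kb_cds >= 0))
  expect_true(all(truth$baseline_mean > 0))
  expect_true(all(substr(sim$regions$cds_seq, 1, 3) == "ATG"))
  last3 <- substr(sim$regions$cds_seq, truth$cds_len - 2, truth$cds_len)
  expect_true(all(last3 %in% c("TAA", "TAG", "TGA")))
  expect_setequal(unique(truth$strand), c("+", "-"))
  expect_true(all(truth$category[truth$compartment != "nuclear"] == "organellar"))
})

test_that("planted motif boosts raise realized density by the planted amount", {
  long_cds <- c(meanlog = log(3000), sdlog = 0.1)
  base_spec <- synthetic_spec(n_genes = 200, seed = 101, rrach_boost = 0,
                              cds_len = long_cds)
  boost_spec <- synthetic_spec(n_genes = 200, seed = 101, rrach_boost = 20,
                               cds_len = long_cds)
  t0 <- simulate_genome(base_spec, assemble = FALSE)$truth
  d20 <- simulate_genome(boost_spec, assemble = FALSE)$truth$rrach_per_kb_cds
  # background alone sits near the analytic i.i.d. expectation at the
  # realized mean adenosine propensity
  a <- mean(t0$a_freq_cds)
  rest <- (1 - a) / 3
  exp_bg <- expected_motif_density("RRACH", c(A = a, C = rest, G = rest, T = rest))
  expect_lt(abs(mean(t0$rrach_per_kb_cds) - exp_bg), 1.5)
  # planting overwrites ~10% of the CDS at boost 20, displacing a small
  # fraction of background matches, so the net gain sits just under 20/kb
  expect_lt(abs(mean(d20) - mean(t0$rrach_per_kb_cds) - 20), 3)
})

test_that("counts follow the planted NB model across groups", {
  spec <- synthetic_spec(n_genes = 120, n_lines = 2, reps_per_group = 4, seed = 7)
  sim <- simulate_genome(spec, assemble = FALSE)
  cs <- simulate_counts(sim$truth, spec)
  expect_equal(dim(cs$counts), c(120L, 12L))
  expect_true(is.integer(cs$counts) || all(cs$counts == round(cs$counts)))
  expect_setequal(unique(unname(cs$group_of)), c("control", "line1", "line2"))
  expect_true(all(cs$size_factors_true >= 0.5 & cs$size_factors_true <= 2))
  # strong planted effects show up in raw group means
  strong <- sim$truth$true_log2fc > 1.5
  if (any(strong)) {
    ctrl <- rowMeans(cs$counts[strong, cs$group_of == "control", drop = FALSE])
    line <- rowMeans(cs$counts[strong, cs$group_of == "line1", drop = FALSE])
    expect_gt(mean(line > ctrl), 0.8)
  }
})

test_that("the dispersion parameter interpolates to the Poisson limit", {
  spec <- synthetic_spec(n_genes = 600, n_lines = 1, reps_per_group = 50,
                         seed = 3, dispersion = 1e-8, beta_motif = 0,
                         category_effects = c(defense = 0, growth = 0, organellar = 0),
                         baseline_mean_dist = c(meanlog = log(500), sdlog = 0))
  sim <- simulate_genome(spec, assemble = FALSE)
  cs <- simulate_counts(sim$truth, spec)
  ctrl <- cs$counts[, cs$group_of == "control", drop = FALSE]
  sf <- cs$size_factors_true[cs$group_of == "control"]
  y <- sweep(ctrl, 2, sf, "/")
  # per-gene variance of scaled counts ~ mean / harmonic-ish factor; ratio ~ 1
  ratio <- apply(y, 1, var) / (rowMeans(y) * mean(1 / sf))
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("a planted motif effect propagates into recovered gene lists", {
  spec <- synthetic_spec(n_genes = 800, n_lines = 1, seed = 23, beta_motif = 1)
  sim <- simulate_genome(spec, assemble = FALSE)
  cs <- simulate_counts(sim$truth, spec)
  de <- classify_de(nb_wald_test(cs$counts, cs$group_of, c("line1", "control")))
  up <- de$gene_id[de$status == "up"]
  down <- de$gene_id[de$status == "down"]
  expect_gt(length(up), 20)
  expect_gt(length(down), 20)
  tr <- sim$truth
  expect_gt(median(tr$rrach_per_kb_cds[tr$gene_id %in% up]),
            median(tr$rrach_per_kb_cds[tr$gene_id %in% down]))
  expect_gt(median(tr$a_freq_cds[tr$gene_id %in% up]),
            median(tr$a_freq_cds[tr$gene_id %in% down]))
})
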
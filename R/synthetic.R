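#' Specification for a synthetic transcriptome experiment
#'
#' Bundles and validates every knob of the generator. The defaults describe
#' the study design the downstream analysis assumes: one wild-type control
#' plus three transgenic lines with six biological replicates each, ~2,000
#' genes with Arabidopsis-like region lengths and adenosine content, a small
#' organellar fraction, defense-like genes pushed down and growth-like genes
#' pushed up in the transgenics, and a fold-change component proportional to
#' each gene's standardized CDS RRACH density.
#'
#' @param n_genes Number of genes.
#' @param n_lines Number of transgenic lines (>= 1).
#' @param reps_per_group Replicates per group (control and each line).
#' @param compartment_probs Named probabilities for `nuclear`, `mito`,
#'   `plastid`; must sum to 1.
#' @param utr5_len,cds_len,utr3_len Log-normal length parameters
#'   `c(meanlog, sdlog)` in bases; CDS lengths are rounded to a multiple of 3
#'   (minimum 90 bases), UTRs floored at 10.
#' @param a_freq_dist Beta parameters `c(shape1, shape2)` for per-gene
#'   adenosine propensity.
#' @param rrach_boost Extra planted RRACH motifs per kb of CDS (>= 0; at most
#'   200, the packing limit for non-overlapping 5-mers).
#' @param beta_motif Log2 fold-change units per standard deviation of CDS
#'   RRACH density.
#' @param category_effects Named log2FC shifts; recognized names are
#'   `defense`, `growth`, `organellar`.
#' @param category_probs Named probabilities for nuclear genes to be
#'   `defense` or `growth` (the rest are uncategorized).
#' @param dispersion NB dispersion alpha (> 0), shared by all genes.
#' @param baseline_mean_dist Log-normal parameters `c(meanlog, sdlog)` for
#'   per-gene baseline mean counts.
#' @param seed Integer seed; the single source of randomness.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 2000L,
                           n_lines = 3L,
                           reps_per_group = 6L,
                           compartment_probs = c(nuclear = 0.94, mito = 0.03, plastid = 0.03),
                           utr5_len = c(meanlog = log(150), sdlog = 0.5),
                           cds_len = c(meanlog = log(1200), sdlog = 0.45),
                           utr3_len = c(meanlog = log(220), sdlog = 0.5),
                           a_freq_dist = c(shape1 = 28, shape2 = 72),
                           rrach_boost = 0,
                           beta_motif = 1,
                           category_effects = c(defense = -1, growth = 1, organellar = -1.5),
                           category_probs = c(defense = 0.08, growth = 0.08),
                           dispersion = 0.05,
                           baseline_mean_dist = c(meanlog = log(100), sdlog = 1),
                           seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
               reps_per_group = as.integer(reps_per_group),
               compartment_probs = compartment_probs,
               utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
               a_freq_dist = a_freq_dist, rrach_boost = rrach_boost,
               beta_motif = beta_motif, category_effects = category_effects,
               category_probs = category_probs, dispersion = dispersion,
               baseline_mean_dist = baseline_mean_dist,
               seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_genes < 1L || n_lines < 1L || reps_per_group < 1L) {
      stop("n_genes, n_lines and reps_per_group must all be >= 1")
    }
    if (!setequal(names(compartment_probs), c("nuclear", "mito", "plastid"))) {
      stop("compartment_probs must be named nuclear/mito/plastid")
    }
    if (abs(sum(compartment_probs) - 1) > 1e-9) {
      stop("compartment_probs must sum to 1")
    }
    if (dispersion <= 0) stop("dispersion must be > 0")
    if (rrach_boost < 0) stop("rrach_boost must be >= 0")
    # a planted motif occupies 5 bases; boost/kb * 5 bases must fit in 1 kb
    if (rrach_boost * 5 > 1000) {
      stop("rrach_boost = ", rrach_boost,
           " cannot fit: planted 5-mers would exceed the CDS length")
    }
    if (sum(category_probs) > 1) stop("category_probs must sum to <= 1")
  })
  invisible(spec)
}

.stop_codons <- c("TAA", "TAG", "TGA")

.random_rrach <- function(n) {
  # concrete instances of the degenerate motif
  r1 <- sample(c("A", "G"), n, replace = TRUE)
  r2 <- sample(c("A", "G"), n, replace = TRUE)
  h <- sample(c("A", "C", "T"), n, replace = TRUE)
  paste0(r1, r2, "AC", h)
}

# Uniformly sample n non-overlapping 5-mer start positions within [lo, hi]
# (combinatorial spacing construction, exact uniform over configurations).
.nonoverlap_starts <- function(n, lo, hi) {
  if (n == 0L) return(integer(0L))
  m <- hi - lo + 1L - 4L * (n - 1L)
  if (m < n) stop("cannot place ", n, " non-overlapping motifs in ", hi - lo + 1L, " bases")
  u <- sort(sample.int(m, n))
  lo - 1L + u + 4L * (seq_len(n) - 1L)
}

#' Simulate a transcriptome: genome FASTA-ready sequences, gene models, truth
#'
#' Generates `n_genes` genes, each a contiguous 5'UTR-CDS-3'UTR block on a
#' randomly chosen strand, tiled along one chromosome with fixed 100-base
#' spacers. Bases are drawn i.i.d. per gene with its Beta-drawn adenosine
#' propensity (C/G/T share the rest equally); the CDS starts with ATG, ends
#' with a stop codon and has length a multiple of 3. When `rrach_boost > 0`,
#' `round(boost * cds_len / 1000)` extra concrete RRACH instances overwrite
#' bases at uniformly chosen non-overlapping CDS positions (never touching
#' the start or stop codon), decoupling motif density from adenosine
#' propensity. The truth table records the *realized* composition measured
#' on the final sequence, plus each gene's planted fold change
#' `beta_motif * z + category_effect` where `z` is the across-gene
#' standardized CDS RRACH density.
#'
#' @param spec A [synthetic_spec].
#' @param assemble Assemble the tiled chromosome and gene models (default
#'   TRUE). `FALSE` returns only `regions` and `truth` — enough for
#'   simulation studies that never touch the FASTA/GFF3 files — and skips
#'   the spacer draws, so realized per-gene sequences are identical either
#'   way under one seed.
#' @return A list: `genome` (named character, one chromosome), `models`
#'   (`gene_models` data frame), `regions` (`transcript_regions` data frame,
#'   mRNA-sense), `truth` (data frame with `gene_id`, `compartment`,
#'   `category`, `strand`, `utr5_len`, `cds_len`, `utr3_len`, `a_freq_cds`,
#'   `rrach_per_kb_cds`, `true_log2fc`, `baseline_mean`, `dispersion`).
#' @export
simulate_genome <- function(spec, assemble = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  n <- spec$n_genes
  motif <- motif_pattern("RRACH")

  compartment <- sample(names(spec$compartment_probs), n, replace = TRUE,
                        prob = spec$compartment_probs)
  p_def <- spec$category_probs[["defense"]]
  p_gro <- spec$category_probs[["growth"]]
  nuclear_cat <- sample(c("defense", "growth", "none"), n, replace = TRUE,
                        prob = c(p_def, p_gro, 1 - p_def - p_gro))
  category <- ifelse(compartment == "nuclear", nuclear_cat, "organellar")

  a_prop <- stats::rbeta(n, spec$a_freq_dist[[1L]], spec$a_freq_dist[[2L]])
  len5 <- pmax(10L, as.integer(round(stats::rlnorm(n, spec$utr5_len[[1L]], spec$utr5_len[[2L]]))))
  lenc <- pmax(90L, as.integer(round(stats::rlnorm(n, spec$cds_len[[1L]], spec$cds_len[[2L]]))))
  lenc <- 3L * as.integer(round(lenc / 3))
  len3 <- pmax(10L, as.integer(round(stats::rlnorm(n, spec$utr3_len[[1L]], spec$utr3_len[[2L]]))))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  baseline <- stats::rlnorm(n, spec$baseline_mean_dist[[1L]], spec$baseline_mean_dist[[2L]])

  gene_ids <- sprintf("g%04d", seq_len(n))
  bases <- c("A", "C", "G", "T")
  utr5_seq <- character(n); cds_seq <- character(n); utr3_seq <- character(n)
  a_freq_cds <- numeric(n); motif_count_cds <- integer(n)
  pos_sets <- motif$positions
  for (i in seq_len(n)) {
    p <- c(a_prop[i], rep((1 - a_prop[i]) / 3, 3L))
    total <- len5[i] + lenc[i] + len3[i]
    draw <- sample(bases, total, replace = TRUE, prob = p)
    u5 <- draw[seq_len(len5[i])]
    cds <- draw[len5[i] + seq_len(lenc[i])]
    u3 <- draw[len5[i] + lenc[i] + seq_len(len3[i])]
    cds[1:3] <- c("A", "T", "G")
    cds[(lenc[i] - 2L):lenc[i]] <- strsplit(sample(.stop_codons, 1L), "")[[1L]]
    n_plant <- as.integer(round(spec$rrach_boost * lenc[i] / 1000))
    if (n_plant > 0L) {
      starts <- .nonoverlap_starts(n_plant, 4L, lenc[i] - 7L)
      inst <- .random_rrach(n_plant)
      for (j in seq_len(n_plant)) {
        cds[starts[j]:(starts[j] + 4L)] <- strsplit(inst[j], "")[[1L]]
      }
    }
    # realized CDS composition, measured on the final base vector
    a_freq_cds[i] <- sum(cds == "A") / lenc[i]
    hit <- (cds %in% pos_sets[[1L]])[seq_len(lenc[i] - 4L)]
    for (k in 2L:5L) {
      hit <- hit & (cds %in% pos_sets[[k]])[k:(lenc[i] - 5L + k)]
    }
    motif_count_cds[i] <- sum(hit)
    utr5_seq[i] <- paste(u5, collapse = "")
    cds_seq[i] <- paste(cds, collapse = "")
    utr3_seq[i] <- paste(u3, collapse = "")
  }
  rrach_cds <- 1000 * motif_count_cds / lenc

  genome <- NULL; models <- NULL
  if (assemble) {
    # tile onto one chromosome with 100-base spacers
    spacer_len <- 100L
    transcripts <- paste0(utr5_seq, cds_seq, utr3_seq)
    minus <- strand == "-"
    if (any(minus)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(transcripts[minus])))
      transcripts[minus] <- rc
    }
    spacers <- vapply(seq_len(n + 1L), function(i) {
      paste(sample(bases, spacer_len, replace = TRUE), collapse = "")
    }, character(1L))
    chrom_parts <- character(2L * n + 1L)
    chrom_parts[seq(1L, 2L * n + 1L, by = 2L)] <- spacers
    chrom_parts[seq(2L, 2L * n, by = 2L)] <- transcripts
    gene_len <- len5 + lenc + len3
    gs <- spacer_len + cumsum(c(0L, gene_len[-n] + spacer_len)) + 1L
    ge <- gs + gene_len - 1L
    # per kind, 1-based inclusive; minus strand stores utr3/cds/utr5 ascending
    first_len <- ifelse(minus, len3, len5)
    third_len <- ifelse(minus, len5, len3)
    models <- data.frame(
      gene_id = rep(gene_ids, each = 3L),
      seq_id = "chr1",
      strand = rep(strand, each = 3L),
      kind = as.vector(rbind(ifelse(minus, "utr3", "utr5"), "cds",
                             ifelse(minus, "utr5", "utr3"))),
      start = as.vector(rbind(gs, gs + first_len, ge - third_len + 1L)),
      end = as.vector(rbind(gs + first_len - 1L, ge - third_len, ge)),
      stringsAsFactors = FALSE)
    rownames(models) <- NULL
    class(models) <- c("gene_models", "data.frame")
    genome <- c(chr1 = paste(chrom_parts, collapse = ""))
  }
  z <- rrach_cds - mean(rrach_cds)
  sd_r <- stats::sd(rrach_cds)
  z <- if (is.na(sd_r) || sd_r == 0) rep(0, n) else z / sd_r
  eff <- stats::setNames(rep(0, n), category)
  for (nm in names(spec$category_effects)) {
    eff[category == nm] <- spec$category_effects[[nm]]
  }
  true_log2fc <- spec$beta_motif * z + unname(eff)

  truth <- data.frame(
    gene_id = gene_ids, compartment = compartment, category = category,
    strand = strand, utr5_len = len5, cds_len = lenc, utr3_len = len3,
    a_freq_cds = a_freq_cds, rrach_per_kb_cds = rrach_cds,
    true_log2fc = true_log2fc, baseline_mean = baseline,
    dispersion = spec$dispersion, stringsAsFactors = FALSE)

  regions <- data.frame(gene_id = gene_ids, utr5_seq = utr5_seq,
                        cds_seq = cds_seq, utr3_seq = utr3_seq,
                        cds_complete = TRUE, stringsAsFactors = FALSE)
  class(regions) <- c("transcript_regions", "data.frame")

  list(genome = genome, models = models, regions = regions, truth = truth)
}

#' Simulate an NB counts matrix from a truth table
#'
#' Counts follow `NB(mean = sf_j * baseline_g * 2^(x_j * true_log2fc_g),
#' dispersion alpha)` with `x_j = 1` for transgenic samples and 0 for the
#' control; per-sample library-size factors are drawn log-uniform in
#' \[0.5, 2\] so the normalization stage has real work to do.
#'
#' @param truth Truth table from [simulate_genome()].
#' @param spec The same [synthetic_spec].
#' @return List: `counts` (integer matrix genes x samples), `group_of`
#'   (named sample -> group, control group `"control"`, lines
#'   `"line1"`...), `size_factors_true` (the drawn factors).
#' @export
simulate_counts <- function(truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"), is.data.frame(truth), nrow(truth) > 0L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed((spec$seed + 1000003L) %% .Machine$integer.max)
  groups <- c("control", paste0("line", seq_len(spec$n_lines)))
  sample_group <- rep(groups, each = spec$reps_per_group)
  sample_ids <- paste0(sample_group, "_rep", rep(seq_len(spec$reps_per_group),
                                                 times = length(groups)))
  n_samp <- length(sample_ids)
  sf <- exp(stats::runif(n_samp, log(0.5), log(2)))
  x <- as.numeric(sample_group != "control")
  mu <- outer(truth$baseline_mean, sf) * 2^(truth$true_log2fc %o% x)
  if (any(!is.finite(mu))) stop("non-finite NB mean; check spec effect sizes")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
                   nrow = nrow(truth),
                   dimnames = list(truth$gene_id, sample_ids))
  list(counts = counts,
       group_of = stats::setNames(sample_group, sample_ids),
       size_factors_true = stats::setNames(sf, sample_ids))
}

#' Write a simulated experiment to disk
#'
#' Emits the genome FASTA (60-column wrap), gene-model GFF3, counts TSV and
#' truth TSV, all byte-deterministic for a fixed spec.
#'
#' @param sim Output of [simulate_genome()].
#' @param counts_sim Output of [simulate_counts()] (optional; skipped if NULL).
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, counts_sim = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(outdir, "genome.fa"),
    gff3 = file.path(outdir, "genes.gff3"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_fasta(sim$genome, paths[["fasta"]])
  write_gff3(sim$models, paths[["gff3"]])
  write_tsv(sim$truth, paths[["truth"]])
  if (!is.null(counts_sim)) {
    paths <- c(paths, counts = file.path(outdir, "counts.tsv"),
               samples = file.path(outdir, "samples.tsv"))
    write_counts(counts_sim$counts, paths[["counts"]])
    write_tsv(data.frame(sample_id = names(counts_sim$group_of),
                         group = unname(counts_sim$group_of),
                         stringsAsFactors = FALSE),
              paths[["samples"]])
  }
  invisible(paths)
}
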
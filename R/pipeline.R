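#' Build and validate a pipeline configuration
#'
#' Every threshold defaults to the analysis it was designed for: DE calls at
#' BH-adjusted p < .01, top-100 per-line lists, 1,000-gene lists when
#' re-analyzing an external DE table, a 1,200-gene random reference set, and
#' a .05 omnibus gate before pairwise tests. Exactly one of `counts` /
#' `external_de` must be supplied: a counts matrix runs the DE stage, an
#' external DE table skips it.
#'
#' @param counts Path to a counts TSV (gene_id + sample columns), or NULL.
#' @param samples Path to a sample table TSV (`sample_id`, `group`); required
#'   with `counts`.
#' @param reference Reference (control) group label; default `"control"`.
#' @param external_de Path to an external DE table TSV (`gene_id`, `log2fc`,
#'   optional `p_raw`, `p_adj`), or NULL.
#' @param fasta,gff3 Paths to the genome FASTA and gene-model GFF3 feeding
#'   the composition stage (optional; composition is skipped without them).
#' @param categories Path to a gene -> category TSV (optional).
#' @param go_annotations Path to a gene -> GO-term-name TSV (optional).
#' @param atlas Path to a gene x tissue expression TSV (optional).
#' @param keywords Keywords for the GO-name screen; default
#'   `c("pathogen", "fungus")`.
#' @param tissue_keywords Substrings defining the tissue class of interest in
#'   the atlas screen; default `"senescent"`.
#' @param de_alpha Adjusted-p threshold for DE classification; default .01.
#' @param top_n Per-line top-list size; default 100.
#' @param external_list_n External up/down/random list size; default 1000.
#' @param random_set_size Random reference set size; default 1200.
#' @param kw_gate Omnibus gate for pairwise tests; default .05.
#' @param motif IUPAC motif; default `"RRACH"`.
#' @param shared_subset Optional character vector naming the transgenic lines
#'   whose intersection is admitted alongside the all-lines intersection; by
#'   default the two lines with the most DE calls.
#' @param seed Integer seed for the random set.
#' @param outdir Output directory for stage tables.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, samples = NULL, reference = "control",
                            external_de = NULL, fasta = NULL, gff3 = NULL,
                            categories = NULL, go_annotations = NULL,
                            atlas = NULL,
                            keywords = c("pathogen", "fungus"),
                            tissue_keywords = "senescent",
                            de_alpha = 0.01, top_n = 100L,
                            external_list_n = 1000L, random_set_size = 1200L,
                            kw_gate = 0.05, motif = "RRACH",
                            shared_subset = NULL,
                            seed = 1L, outdir = "rrachstrat_out") {
  if (is.null(counts) == is.null(external_de)) {
    stop("config error: exactly one of 'counts' and 'external_de' is required")
  }
  if (!is.null(counts) && is.null(samples)) {
    stop("config error: 'samples' table is required with 'counts'")
  }
  for (th in c(de_alpha, top_n, external_list_n, random_set_size, kw_gate)) {
    if (!is.numeric(th) || th <= 0) stop("config error: thresholds must be positive")
  }
  structure(list(counts = counts, samples = samples, reference = reference,
                 external_de = external_de, fasta = fasta, gff3 = gff3,
                 categories = categories, go_annotations = go_annotations,
                 atlas = atlas, keywords = keywords,
                 tissue_keywords = tissue_keywords,
                 de_alpha = de_alpha, top_n = as.integer(top_n),
                 external_list_n = as.integer(external_list_n),
                 random_set_size = as.integer(random_set_size),
                 kw_gate = kw_gate, motif = motif,
                 shared_subset = shared_subset,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path Path to a YAML file whose keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

.flatten_comparison <- function(cmp, region_kind) {
  base <- data.frame(metric = cmp$metric_name, region = region_kind,
                     kw_statistic = cmp$kw_statistic, kw_p = cmp$kw_p,
                     stringsAsFactors = FALSE)
  if (is.null(cmp$pairwise)) {
    base$group_i <- NA_character_; base$group_j <- NA_character_
    base$raw_p <- NA_real_; base$adj_p <- NA_real_
    return(base)
  }
  cbind(base[rep(1L, nrow(cmp$pairwise)), , drop = FALSE],
        cmp$pairwise[, c("group_i", "group_j", "raw_p", "adj_p")])
}

#' Run the full analysis pipeline
#'
#' Stage order: (simulated or real) counts -> DE per line -> directional and
#' top-n gene lists -> multi-line shared lists and overlap tests ->
#' composition of up/down/random transcript sets -> enrichment screens ->
#' gated group comparisons. With an external DE table the DE stage is
#' skipped and balanced up/down/random lists are drawn instead. Every stage
#' table is written as a TSV under `config$outdir`; re-running an identical
#' config reproduces identical tables.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list with the in-memory stage tables (`de`,
#'   `sets`, `overlaps`, `composition`, `comparisons`, `enrichment`,
#'   `screens`), the written `paths`, and the run `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0L)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message("[rrachstrat] ", line)
  }
  report <- list(paths = character(0L))

  ## ---- lists stage (DE or external) ----
  if (!is.null(config$counts)) {
    counts <- read_counts(config$counts)
    sample_tab <- utils::read.delim(config$samples, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% names(sample_tab))) {
      stop("input-schema error in ", config$samples,
           ": need columns sample_id, group")
    }
    group_of <- stats::setNames(sample_tab$group, sample_tab$sample_id)
    if (!all(colnames(counts) %in% names(group_of))) {
      stop("input-schema error: counts samples missing from ", config$samples)
    }
    lines <- setdiff(unique(group_of[colnames(counts)]), config$reference)
    if (length(lines) == 0L) stop("de stage: no non-reference group")
    note("DE stage: ", length(lines), " contrast(s) vs ", config$reference,
         " on ", nrow(counts), " genes")
    de_tables <- lapply(lines, function(ln) {
      classify_de(nb_wald_test(counts, group_of, c(ln, config$reference)),
                  alpha = config$de_alpha)
    })
    names(de_tables) <- lines
    de_all <- do.call(rbind, de_tables)
    n_de <- vapply(de_tables, function(d) sum(d$status %in% c("up", "down")),
                   integer(1L))
    for (ln in lines) {
      note("line ", ln, ": ", sum(de_tables[[ln]]$status == "up"), " up, ",
           sum(de_tables[[ln]]$status == "down"), " down at adj p < ",
           config$de_alpha)
    }

    subset_lines <- config$shared_subset %||%
      names(sort(n_de, decreasing = TRUE))[seq_len(min(2L, length(lines)))]
    note("shared-list subset: ", paste(subset_lines, collapse = ", "))

    dir_sets <- function(direction) {
      per_line <- lapply(lines, function(ln) {
        d <- de_tables[[ln]]
        gene_set(paste0(ln, "_", direction),
                 d$gene_id[d$status == direction], direction = direction,
                 provenance = list(line = ln, alpha = config$de_alpha))
      })
      names(per_line) <- lines
      per_line
    }
    up_by_line <- dir_sets("up")
    down_by_line <- dir_sets("down")
    shared_up <- if (length(lines) >= 2L) {
      shared_set(up_by_line, "all_or_subset",
                 subset = paste0(subset_lines, "_up"), name = "shared_up")
    } else up_by_line[[1L]]
    shared_down <- if (length(lines) >= 2L) {
      shared_set(down_by_line, "all_or_subset",
                 subset = paste0(subset_lines, "_down"), name = "shared_down")
    } else down_by_line[[1L]]
    note("shared lists: ", length(shared_up), " up, ", length(shared_down), " down")

    top_up <- lapply(lines, function(ln) {
      top_n_by_lfc(de_tables[[ln]], config$top_n, "up", name = paste0(ln, "_top_up"))
    })
    top_down <- lapply(lines, function(ln) {
      top_n_by_lfc(de_tables[[ln]], config$top_n, "down", name = paste0(ln, "_top_down"))
    })
    names(top_up) <- names(top_down) <- lines

    overlaps <- list()
    if (length(lines) >= 2L) {
      pairs <- utils::combn(lines, 2L, simplify = FALSE)
      for (pr in pairs) {
        d1 <- de_tables[[pr[[1L]]]]; d2 <- de_tables[[pr[[2L]]]]
        M <- length(intersect(d1$gene_id[d1$status != "na"],
                              d2$gene_id[d2$status != "na"]))
        for (direction in c("up", "down")) {
          tl <- if (direction == "up") top_up else top_down
          ot <- overlap_test(tl[[pr[[1L]]]], tl[[pr[[2L]]]], M)
          overlaps[[paste(pr[[1L]], pr[[2L]], direction, sep = "_")]] <- ot
        }
      }
    }
    universe <- rownames(counts)
    de_main <- de_tables[[subset_lines[[1L]]]]
    up_set <- shared_up; down_set <- shared_down
    report$de <- de_all
    report$paths["de"] <- write_tsv(de_all, file.path(config$outdir, "de_table.tsv"))
  } else {
    de_ext <- read_de_table(config$external_de)
    note("external DE table: ", nrow(de_ext), " genes; building balanced lists of ",
         config$external_list_n)
    ext <- external_de_lists(de_ext, config$external_list_n, seed = config$seed)
    up_set <- ext$up; down_set <- ext$down
    universe <- de_ext$gene_id
    de_main <- de_ext
    overlaps <- list()
    report$de <- de_ext
  }

  rand_n <- min(config$random_set_size, length(universe))
  if (rand_n < config$random_set_size) {
    note("random set truncated to universe size ", rand_n)
  }
  random_set <- random_gene_set(universe, rand_n,
                                seed = (config$seed + 20011L) %% .Machine$integer.max,
                                name = "random")
  sets <- list(down = down_set, random = random_set, up = up_set)
  set_table <- do.call(rbind, lapply(sets, function(s) {
    data.frame(set = s$name, direction = s$direction, gene_id = s$genes,
               stringsAsFactors = FALSE)
  }))
  report$sets <- sets
  report$paths["sets"] <- write_tsv(set_table, file.path(config$outdir, "gene_sets.tsv"))

  if (length(overlaps) > 0L) {
    ov_tab <- do.call(rbind, lapply(names(overlaps), function(nm) {
      o <- overlaps[[nm]]
      data.frame(comparison = nm, k = o$k_observed, n_a = o$n_a, n_b = o$n_b,
                 universe = o$universe_size, expected = o$expected,
                 p_upper = o$p_upper, stringsAsFactors = FALSE)
    }))
    report$overlaps <- ov_tab
    report$paths["overlaps"] <- write_tsv(ov_tab, file.path(config$outdir, "overlaps.tsv"))
  }

  ## ---- composition stage ----
  comparisons_tab <- NULL
  if (!is.null(config$fasta) && !is.null(config$gff3)) {
    genome <- read_fasta(config$fasta)
    models <- read_gff3(config$gff3)
    regions <- extract_regions(models, genome)
    profiles <- composition_table(regions, motif = config$motif)
    note("composition: ", length(unique(profiles$gene_id)), " genes profiled")
    report$composition <- profiles
    report$paths["composition"] <-
      write_tsv(profiles, file.path(config$outdir, "composition.tsv"))

    cmp_rows <- list()
    for (metric in c("a_freq", "length", "motif_per_kb")) {
      for (region_kind in intersect(c("utr5", "cds", "utr3"),
                                    unique(profiles$region_kind))) {
        usable <- vapply(sets, function(s) {
          any(s$genes %in% profiles$gene_id[profiles$region_kind == region_kind])
        }, logical(1L))
        if (!all(usable)) next
        cmp <- suppressMessages(compare_metric_across_sets(
          profiles, sets, metric = metric, region_kind = region_kind,
          gate_p = config$kw_gate))
        cmp_rows[[paste(metric, region_kind)]] <- .flatten_comparison(cmp, region_kind)
      }
    }
    comparisons_tab <- do.call(rbind, cmp_rows)
    rownames(comparisons_tab) <- NULL
    report$comparisons <- comparisons_tab
    report$paths["comparisons"] <-
      write_tsv(comparisons_tab, file.path(config$outdir, "comparisons.tsv"))
  } else {
    note("composition stage skipped (no FASTA/GFF3)")
  }

  ## ---- enrichment stage ----
  if (!is.null(config$categories)) {
    cat_tab <- read_annotation(config$categories)
    enr_rows <- list()
    for (set_nm in c("up", "down")) {
      s <- sets[[set_nm]]
      s2 <- gene_set(s$name, intersect(s$genes, universe), s$direction)
      if (length(s2$genes) == 0L) next
      for (cat_nm in unique(cat_tab$label)) {
        members <- intersect(cat_tab$gene_id[cat_tab$label == cat_nm], universe)
        if (length(members) == 0L) next
        e <- category_enrichment(s2, members, universe)
        enr_rows[[paste(set_nm, cat_nm)]] <- data.frame(
          set = s$name, category = cat_nm, k = e$k, n = e$n, K = e$K, M = e$M,
          fold = e$fold, p_upper = e$p_upper, stringsAsFactors = FALSE)
      }
    }
    if (length(enr_rows) > 0L) {
      enr_tab <- do.call(rbind, enr_rows)
      enr_tab$p_adj <- bh_adjust(enr_tab$p_upper)
      rownames(enr_tab) <- NULL
      report$enrichment <- enr_tab
      report$paths["enrichment"] <-
        write_tsv(enr_tab, file.path(config$outdir, "enrichment.tsv"))
      note("enrichment: ", nrow(enr_tab), " set x category tests")
    }
  }

  screens <- list()
  if (!is.null(config$go_annotations)) {
    go_tab <- read_annotation(config$go_annotations)
    scr <- suppressMessages(
      keyword_screen(sets$up, sets$down, go_tab, config$keywords))
    screens$keyword <- scr
    note("keyword screen (", paste(config$keywords, collapse = "/"), "): p = ",
         format(scr$p, digits = 3))
  }
  if (!is.null(config$atlas)) {
    atlas <- read_atlas(config$atlas)
    assign <- tissue_max_assignment(atlas)
    hit_tissues <- colnames(atlas)[Reduce(`|`, lapply(
      config$tissue_keywords,
      function(kw) grepl(kw, colnames(atlas), ignore.case = TRUE)))]
    members <- names(assign)[!is.na(assign) & assign %in% hit_tissues]
    scr <- membership_screen(sets$up, sets$down, members)
    screens$tissue <- scr
    note("tissue screen (", paste(config$tissue_keywords, collapse = "/"),
         "): p = ", format(scr$p, digits = 3))
  }
  if (length(screens) > 0L) {
    scr_tab <- do.call(rbind, lapply(names(screens), function(nm) {
      s <- screens[[nm]]
      data.frame(screen = nm,
                 a_match = s$table[1L, 1L], a_nomatch = s$table[1L, 2L],
                 b_match = s$table[2L, 1L], b_nomatch = s$table[2L, 2L],
                 p = s$p, stringsAsFactors = FALSE)
    }))
    report$screens <- screens
    report$paths["screens"] <- write_tsv(scr_tab, file.path(config$outdir, "screens.tsv"))
  }

  report$log <- log_lines
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  report$paths["log"] <- file.path(config$outdir, "run_log.txt")
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("rrachstrat run report\n")
  for (line in x$log) cat(" ", line, "\n")
  cat("tables:", paste(basename(unname(x$paths)), collapse = ", "), "\n")
  invisible(x)
}
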
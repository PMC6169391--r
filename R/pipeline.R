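#' Configuration of a full pipeline run
#'
#' Bundles everything one reproducible run needs: output directory, master
#' seed, synthetic-data configuration (when simulating), finder parameters,
#' scoring and test options, and optional external inputs. All stage
#' randomness derives from the single seed.
#'
#' @param outdir run directory (created by [run_pipeline()]).
#' @param seed master seed.
#' @param synthetic a [synthetic_config()]; its seed is overridden by
#'   `seed`.
#' @param finder a [finder_params()].
#' @param pssm_mode scoring mode for acceptor scores.
#' @param stats_null null model for the scaffold-distribution test:
#'   `"uniform"` across locations or `"length"`-proportional.
#' @param counts_tsv screen counts TSV (columns `line_id`, `locus_label`,
#'   `n_screened`, `n_events`); default: the bundled screen table.
#' @param arms_tsv optional scaffold-to-chromosome-arm TSV.
#' @return object of class `run_config`.
#' @export
run_config <- function(outdir,
                       seed = 1L,
                       synthetic = synthetic_config(seed = seed),
                       finder = finder_params(),
                       pssm_mode = c("frequency", "consensus"),
                       stats_null = c("uniform", "length"),
                       counts_tsv = NULL,
                       arms_tsv = NULL) {
  pssm_mode <- match.arg(pssm_mode)
  stats_null <- match.arg(stats_null)
  synthetic$seed <- as.integer(seed)
  for (p in c(counts_tsv, arms_tsv)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 synthetic = synthetic, finder = finder,
                 pssm_mode = pssm_mode, stats_null = stats_null,
                 counts_tsv = counts_tsv, arms_tsv = arms_tsv),
            class = "run_config")
}

#' Serialise / load a run configuration (YAML)
#'
#' @param config a [run_config()].
#' @param path YAML path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   `run_config` equal to the one written.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$synthetic <- unclass(x$synthetic)
  x$finder <- unclass(x$finder)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(outdir = x$outdir, seed = x$seed,
             synthetic = do.call(synthetic_config, x$synthetic[
               setdiff(names(x$synthetic), character(0))]),
             finder = do.call(finder_params, x$finder),
             pssm_mode = x$pssm_mode, stats_null = x$stats_null,
             counts_tsv = x$counts_tsv, arms_tsv = x$arms_tsv)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  x <- unclass(config)
  x$outdir <- NULL  # hash is path-independent
  x$synthetic <- unclass(x$synthetic)
  x$finder <- unclass(x$finder)
  yaml::write_yaml(x, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full promoter-trap analysis pipeline
#'
#' Executes the stages in dependency order -- simulate (genome, insertions,
#' splinkerette flanks, reads), find-junctions, annotate, acceptor-matrix,
#' stats -- writing every stage's outputs as headered TSV/FASTA/FASTQ/GFF3
#' files into the run directory, then a consolidated report and a checksum
#' manifest. Rerunning with the same configuration and seed reproduces the
#' checksums.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all stage results and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  hdr <- function(stage) {
    sprintf("traptag %s | stage=%s | seed=%d | config=%s",
            as.character(utils::packageVersion("traptag")), stage,
            config$seed, hash)
  }
  pth <- function(f) file.path(config$outdir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  elements <- default_elements()

  ## stage 1: simulate
  sim <- stage("simulate", {
    gen <- generate_genome(config$synthetic)
    planted <- plant_insertions(gen, elements)
    flanks <- simulate_splinkerette(gen$genome, planted$truth, elements,
                                    enzyme = config$synthetic$enzyme)
    reads <- simulate_reads(gen, planted$truth, elements)
    write_genome_fasta(gen$genome, pth("genome.fasta"))
    write_annotation_gff3(gen$models, pth("annotation.gff3"))
    write_genome_fasta(planted$modified, pth("genome_with_insertions.fasta"))
    write_trap_tsv(reads$truth, pth("truth.tsv"), hdr("simulate"))
    write_flanks_fasta(flanks, pth("flanks.fasta"))
    write_fastq(reads$r1, pth("reads_R1.fastq"))
    write_fastq(reads$r2, pth("reads_R2.fastq"))
    list(gen = gen, truth = reads$truth, flanks = flanks,
         r1 = reads$r1, r2 = reads$r2)
  })

  ## stage 2: find-junctions
  junctions <- stage("find-junctions", {
    reporter <- elements$non_IRES$reporter_orf
    hits <- scan_read_pairs(sim$r1, sim$r2, reporter, config$finder)
    located <- locate_junction(hits, sim$gen$genome, sim$gen$models,
                               config$finder)
    tab2 <- aggregate_junctions(located)
    write_trap_tsv(located, pth("junction_hits.tsv"), hdr("find-junctions"))
    write_trap_tsv(tab2, pth("junction_table.tsv"), hdr("find-junctions"))
    list(hits = located, table = tab2)
  })

  ## stage 3: annotate
  annotation <- stage("annotate", {
    recs <- map_flanks(sim$flanks, elements$non_IRES, sim$gen$genome)
    calls <- call_features(recs[recs$status == "ok", ], sim$gen$models)
    arms <- if (!is.null(config$arms_tsv)) read_trap_tsv(config$arms_tsv)
    tab <- tabulate_insertions(calls, arms)
    write_trap_tsv(recs, pth("insertion_records.tsv"), hdr("annotate"))
    write_trap_tsv(calls, pth("feature_calls.tsv"), hdr("annotate"))
    write_trap_tsv(tab$by_class, pth("feature_summary.tsv"), hdr("annotate"))
    write_insertion_bed(calls, pth("insertions.bed"))
    list(records = recs, calls = calls, tabulation = tab)
  })

  ## stage 4: acceptor matrix
  pssm <- stage("pssm", {
    windows <- extract_acceptor_windows(sim$gen$models, sim$gen$genome)
    m <- build_acceptor_matrix(windows)
    scores <- data.frame(
      acceptor = c("planned_3pSA", "unplanned_3pSA", "consensus"),
      sequence = c(config$finder$planned_sa_context,
                   config$finder$unplanned_sa_context, m$consensus),
      score = c(score_acceptor(m, config$finder$planned_sa_context,
                               config$pssm_mode),
                score_acceptor(m, config$finder$unplanned_sa_context,
                               config$pssm_mode),
                score_acceptor(m, m$consensus, config$pssm_mode)),
      max_score = m$max_score)
    write_acceptor_matrix(m, pth("acceptor_matrix.tsv"))
    write_trap_tsv(scores, pth("acceptor_scores.tsv"), hdr("pssm"))
    list(matrix = m, scores = scores)
  })

  ## stage 5: stats
  stats_out <- stage("stats", {
    counts_path <- config$counts_tsv %||%
      system.file("extdata", "screen_counts.tsv", package = "traptag")
    counts <- read_trap_tsv(counts_path)
    remob <- remobilization_table(counts)

    calls <- annotation$calls
    genic <- calls[!is.na(calls$gene_id), , drop = FALSE]
    loc_counts <- table(annotation$calls$scaffold)
    hop <- if (length(loc_counts) >= 2L) {
      props <- if (config$stats_null == "length") {
        len <- nchar(sim$gen$genome[names(loc_counts)])
        len / sum(len)
      } else NULL
      suppressWarnings(chisq_gof(as.vector(loc_counts), props))
    }
    intronic <- genic[!is.na(genic$intron_ordinal), , drop = FALSE]
    ipos <- if (nrow(intronic) >= 2L) {
      intron_position_test(intronic$intron_ordinal, intronic$n_introns)
    }
    utr5 <- genic[genic$feature_class == "five_prime_utr_intron" &
                    !is.na(genic$distance_to_orf_start), , drop = FALSE]
    dsum <- if (nrow(utr5)) distance_summary(utr5$distance_to_orf_start)

    write_trap_tsv(remob, pth("remobilization.tsv"), hdr("stats"))
    tests <- data.frame(
      test = c(if (!is.null(hop)) "scaffold_distribution",
               if (!is.null(ipos)) "intron_position"),
      chi2 = c(if (!is.null(hop)) hop$chi2, if (!is.null(ipos)) ipos$chi2),
      df = c(if (!is.null(hop)) hop$df, if (!is.null(ipos)) ipos$df),
      p = c(if (!is.null(hop)) hop$p, if (!is.null(ipos)) ipos$p))
    write_trap_tsv(tests, pth("tests.tsv"), hdr("stats"))
    if (!is.null(dsum)) write_trap_tsv(dsum, pth("distances.tsv"), hdr("stats"))
    list(remobilization = remob, hop = hop, intron_position = ipos,
         distances = dsum)
  })

  results <- list(sim = sim, junctions = junctions, annotation = annotation,
                  pssm = pssm, stats = stats_out, config = config)
  write_report(results, pth("report.md"))

  files <- sort(setdiff(list.files(config$outdir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$outdir, files))))
  write_trap_tsv(manifest, pth("manifest.tsv"))
  results$paths <- stats::setNames(file.path(config$outdir, c(files, "manifest.tsv")),
                                   c(files, "manifest.tsv"))
  invisible(results)
}

# BED (0-based half-open) of insertion sites, converted at the boundary
# from the 1-based fully-closed internal convention.
write_insertion_bed <- function(calls, path) {
  ok <- calls[!is.na(calls$ttaa_start), , drop = FALSE]
  bed <- data.frame(ok$scaffold, ok$ttaa_start - 1L, ok$ttaa_start + 3L,
                    ok$insertion_id, 0L, ok$element_strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the consolidated run report
#'
#' Markdown report whose sections mirror a screen write-up: remobilization
#' frequencies, the junction occurrence table, the insertion feature
#' tabulation, insertion distances, and the chi-square tests. Numbers are
#' taken directly from the stage results (the same objects written to the
#' stage TSVs), so the report cannot drift from the stage outputs.
#'
#' @param results stage results from [run_pipeline()] (any subset of
#'   components; sections without data are omitted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  has <- function(x) !is.null(x)
  if (!any(vapply(results[c("sim", "junctions", "annotation", "pssm", "stats")],
                  has, logical(1)))) {
    stop("no stage outputs to report")
  }
  fmt_df <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 6))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1L, paste, collapse = " | "))
  }
  lines <- c("# Promoter-trap screen report", "")
  if (has(results$config)) {
    lines <- c(lines, sprintf("seed: %d; config: %s", results$config$seed,
                              config_hash(results$config)), "")
  }
  if (has(results$stats) && has(results$stats$remobilization)) {
    lines <- c(lines, "## Remobilization frequencies", "",
               fmt_df(results$stats$remobilization), "")
  }
  if (has(results$junctions)) {
    lines <- c(lines, "## Reporter-fusion junction events", "",
               sprintf("read pairs classified as fusions: %d",
                       nrow(results$junctions$hits)), "",
               fmt_df(results$junctions$table), "")
  }
  if (has(results$annotation)) {
    tab <- results$annotation$tabulation
    recs <- results$annotation$records
    lines <- c(lines, "## Insertion features", "",
               sprintf("flanks mapped: %d of %d; insertions called: %d",
                       sum(recs$status == "ok"), nrow(recs), tab$n_calls), "",
               fmt_df(tab$by_class), "",
               "Intronic insertions by intron ordinal:", "",
               fmt_df(tab$by_ordinal), "")
    if (has(results$sim)) {
      truth <- results$sim$truth
      calls <- results$annotation$calls
      idx <- match(calls$insertion_id, truth$insertion_id)
      agree <- calls$ttaa_start == truth$ttaa_start[idx] &
        calls$element_strand == truth$element_strand[idx] &
        calls$feature_class == truth$true_feature_class[idx]
      lines <- c(lines, sprintf(
        "truth recovery: %d of %d planted insertions (%.1f%%)",
        sum(agree), nrow(truth), 100 * sum(agree) / nrow(truth)), "")
    }
  }
  if (has(results$stats) && has(results$stats$distances)) {
    lines <- c(lines, "## Insertion distances upstream of the ORF +1 (5'-UTR introns)",
               "", fmt_df(results$stats$distances), "")
  }
  if (has(results$pssm)) {
    lines <- c(lines, "## Splice-acceptor scores", "",
               fmt_df(results$pssm$scores), "")
  }
  if (has(results$stats)) {
    tests <- list(scaffold_distribution = results$stats$hop,
                  intron_position = results$stats$intron_position)
    tests <- tests[!vapply(tests, is.null, logical(1))]
    if (length(tests)) {
      df <- data.frame(test = names(tests),
                       chi2 = vapply(tests, `[[`, 0, "chi2"),
                       df = vapply(tests, `[[`, 0L, "df"),
                       p = vapply(tests, `[[`, 0, "p"))
      lines <- c(lines, "## Chi-square tests", "", fmt_df(df), "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
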
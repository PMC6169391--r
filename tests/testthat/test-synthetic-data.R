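test_that("generation is deterministic: identical config and seed give byte-identical outputs", {
  cfg <- tiny_config(seed = 21L)
  run_once <- function() {
    els <- default_elements()
    gen <- generate_genome(cfg)
    pl <- plant_insertions(gen, els)
    rd <- simulate_reads(gen, pl$truth, els)
    fa <- tempfile(fileext = ".fasta"); gf <- tempfile(fileext = ".gff3")
    fq <- tempfile(fileext = ".fastq")
    write_genome_fasta(gen, fa)
    write_annotation_gff3(gen$models, gf)
    write_fastq(rd$r1, fq)
    out <- list(fa = readLines(fa), gf = readLines(gf), fq = readLines(fq),
                truth = rd$truth)
    unlink(c(fa, gf, fq))
    out
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$fa, b$fa)
  # the GFF3 ##date header line is run-date metadata, not content
  expect_identical(grep("^##date", a$gf, value = TRUE, invert = TRUE),
                   grep("^##date", b$gf, value = TRUE, invert = TRUE))
  expect_identical(a$fq, b$fq)
  expect_identical(a$truth, b$truth)
})

test_that("the 5'-UTR intron gene count is forced to round(frac * n_genes)", {
  cfg <- tiny_config(seed = 22L, n_genes = 10L, frac_utr_intron = 0.5)
  gen <- generate_genome(cfg)
  expect_identical(sum(gen$models$genes$has_utr_intron), 5L)
  # every gene has at least one intron
  n_int <- vapply(gen$models$genes$gene_id,
                  function(g) nrow(gene_introns(gen$models, g)), integer(1))
  expect_true(all(n_int >= 1L))
})

test_that("a degenerate intron length range pins every annotated intron length (GFF3 parse check)", {
  cfg <- tiny_config(seed = 23L, frac_utr_intron = 0,
                     intron_length_range = c(500L, 500L))
  gen <- generate_genome(cfg)
  gf <- tempfile(fileext = ".gff3")
  write_annotation_gff3(gen$models, gf)
  models <- read_gene_models(gf)
  unlink(gf)
  lens <- unlist(lapply(models$genes$gene_id, function(g) {
    ints <- gene_introns(models, g)
    ints$end - ints$start + 1L
  }))
  expect_gt(length(lens), 0L)
  expect_true(all(lens == 500L))
})

test_that("introns carry canonical splice signals and a TTAA target site", {
  w <- tiny_world()
  for (gid in w$gen$models$genes$gene_id) {
    gi <- w$gen$models$genes[w$gen$models$genes$gene_id == gid, ]
    ints <- gene_introns(w$gen$models, gid)
    sc <- w$gen$genome[[gi$scaffold]]
    for (k in seq_len(nrow(ints))) {
      iseq <- substr(sc, ints$start[k], ints$end[k])
      if (gi$strand == "-") iseq <- revcomp(iseq)
      expect_identical(substr(iseq, 1L, 2L), "GT")
      expect_identical(substr(iseq, nchar(iseq) - 1L, nchar(iseq)), "AG")
      expect_true(grepl("TTAA", iseq, fixed = TRUE))
    }
  }
})

test_that("truth records verify against the emitted sequences", {
  w <- tiny_world()
  cfg <- w$cfg
  expect_identical(nrow(w$truth), 2L * cfg$n_insertions_per_construct)
  expect_setequal(unique(w$truth$construct), c("IRES", "non_IRES"))
  expect_setequal(unique(stats::na.omit(w$truth$orientation)),
                  c("same_strand", "opposite_strand"))
  for (i in seq_len(nrow(w$truth))) {
    tr <- w$truth[i, ]
    # TTAA at the recorded coordinate of the unmodified genome
    expect_identical(substr(w$gen$genome[[tr$scaffold]], tr$ttaa_start,
                            tr$ttaa_start + 3L), "TTAA")
    # element integrated with target-site duplication in the modified FASTA
    eseq <- element_sequence(w$els[[tr$construct]])
    if (tr$element_strand == "-") eseq <- revcomp(eseq)
    probe <- paste0("TTAA", substr(eseq, 1L, 40L))
    expect_true(grepl(probe, w$modified[[tr$scaffold]], fixed = TRUE))
    probe2 <- paste0(substr(eseq, nchar(eseq) - 39L, nchar(eseq)), "TTAA")
    expect_true(grepl(probe2, w$modified[[tr$scaffold]], fixed = TRUE))
  }
})

test_that("the reporter marker and IRES tag are scrubbed from the genome", {
  w <- tiny_world()
  mu <- verify_marker_uniqueness(w$gen$genome, w$els$non_IRES$reporter_orf, 14L)
  expect_true(mu$unique)
  expect_identical(nrow(mu$hits), 0L)
  expect_identical(nrow(match_genome(w$els$IRES$ires_tag, w$gen$genome)), 0L)
})

test_that("annotation round-trips exactly through GFF3", {
  w <- tiny_world()
  gf <- tempfile(fileext = ".gff3")
  write_annotation_gff3(w$gen$models, gf)
  m2 <- read_gene_models(gf)
  unlink(gf)
  norm <- function(df) {
    df <- df[order(df$gene_id, df$type, df$start), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(norm(m2$features), norm(w$gen$models$features))
  ga <- w$gen$models$genes[order(w$gen$models$genes$gene_id), ]
  gb <- m2$genes[order(m2$genes$gene_id), ]
  rownames(ga) <- rownames(gb) <- NULL
  expect_equal(gb, ga[, names(gb)])
})

test_that("read simulation respects counts, chimera fraction and orientation rules", {
  w <- tiny_world()
  expect_identical(length(w$r1), w$cfg$n_read_pairs)
  expect_identical(length(w$r2), w$cfg$n_read_pairs)
  expect_identical(length(chimeric_ids(w$truth)),
                   as.integer(round(w$cfg$chimera_fraction * w$cfg$n_read_pairs)))

  # chimera_fraction = 0: no read contains the reporter marker
  cfg0 <- tiny_config(seed = 24L, chimera_fraction = 0)
  w0 <- make_world(cfg0, "nochim")
  marker <- substr(w0$els$non_IRES$reporter_orf, 1L, 14L)
  hits <- grepl(marker, c(w0$r1, w0$r2), fixed = TRUE) |
    grepl(revcomp(marker), c(w0$r1, w0$r2), fixed = TRUE)
  expect_identical(sum(hits), 0L)

  # opposite-strand insertions refuse to produce fusion transcripts
  opp <- w$truth[!is.na(w$truth$orientation) &
                   w$truth$orientation == "opposite_strand", ][1, ]
  expect_error(
    fusion_transcript(w$gen$models, w$gen$genome, opp, w$els[[opp$construct]]),
    "non-reporting")
  expect_identical(opp$chimeric_read_ids, "")
})

test_that("IRES-construct fusion reads carry the retained 15-nt tag at the reporter +1", {
  w <- tiny_world()
  tag <- w$els$IRES$ires_tag
  probe <- paste0(tag, substr(w$els$IRES$reporter_orf, 1L, 10L))
  ires_rows <- w$truth[w$truth$construct == "IRES" &
                         nchar(w$truth$chimeric_read_ids) > 0, ]
  expect_gt(nrow(ires_rows), 0L)
  for (ids in strsplit(ires_rows$chimeric_read_ids, ",")) {
    for (id in ids) {
      reads <- c(w$r1[[id]], w$r2[[id]])
      found <- any(grepl(probe, reads, fixed = TRUE) |
                     grepl(revcomp(probe), reads, fixed = TRUE))
      expect_true(found)
    }
  }
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(frac_utr_intron = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(intron_length_range = c(500, 80)), "ordered pair")
  expect_error(synthetic_config(n_genes = -1), "non-negative")
  # sizing error: genome too small for the requested genes
  expect_error(
    generate_genome(synthetic_config(seed = 1, n_scaffolds = 1L,
                                     scaffold_length = 9000L, n_genes = 10L,
                                     utr_intron_5p_distance_range = c(183L, 2000L))),
    "too short")
})
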
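test_that("splinkerette flanks round-trip to the planted insertion records", {
  w <- tiny_world()
  recs <- map_flanks(w$flanks, w$els$non_IRES, w$gen$genome)
  ok <- recs[recs$status == "ok", ]
  # every insertion recovered by at least one flank; every mapped flank exact
  expect_true(all(w$truth$insertion_id %in% ok$insertion_id))
  idx <- match(ok$insertion_id, w$truth$insertion_id)
  expect_identical(ok$scaffold, w$truth$scaffold[idx])
  expect_identical(ok$ttaa_start, w$truth$ttaa_start[idx])
  expect_identical(ok$element_strand, w$truth$element_strand[idx])
  expect_true(all(ok$junction_ttaa_ok))
})

test_that("feature calls agree with the truth classes, ordinals and distances", {
  w <- tiny_world()
  recs <- map_flanks(w$flanks, w$els$non_IRES, w$gen$genome)
  calls <- call_features(recs[recs$status == "ok", ], w$gen$models)
  expect_identical(nrow(calls), nrow(w$truth))
  idx <- match(calls$insertion_id, w$truth$insertion_id)
  expect_identical(calls$feature_class, w$truth$true_feature_class[idx])
  expect_equal(calls$intron_ordinal, w$truth$true_intron_ordinal[idx])
  expect_equal(calls$distance_to_orf_start,
               w$truth$true_distance_to_orf_start[idx])
  genic <- !is.na(calls$gene_id)
  expect_identical(calls$gene_id[genic], w$truth$true_gene_id[idx][genic])
  # reporting orientation corresponds to same-strand truth
  expect_identical(calls$reporting_orientation[genic],
                   w$truth$orientation[idx][genic] == "same_strand")
  # intergenic calls carry no gene id
  inter <- calls$feature_class == "intergenic"
  expect_true(all(is.na(calls$gene_id[inter])))
})

test_that("ambiguous and corrupted flanks are rejected or flagged", {
  els <- default_elements()
  eseq <- element_sequence(els$non_IRES)
  tag3 <- substr(eseq, nchar(eseq) - 29L, nchar(eseq))
  set.seed(55)
  seg <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  # duplicated genomic segment: the flank matches twice
  dup_genome <- c(chr = paste0("TTAA", seg, strrep("AC", 40), "TTAA", seg))
  flank <- paste0(tag3, "TTAA", substr(seg, 1, 80))
  expect_error(map_flank(flank, els$non_IRES, dup_genome), "ambiguous.*2")

  # junction not TTAA: flagged, not dropped
  genome2 <- c(chr = paste0(strrep("GA", 30), "TTAC", seg))
  flank2 <- paste0(tag3, "TTAC", substr(seg, 1, 80))
  expect_warning(rec <- map_flank(flank2, els$non_IRES, genome2), "TTAC")
  expect_false(rec$junction_ttaa_ok)
  expect_identical(rec$ttaa_start, 61L)

  # no recognizable element tag
  expect_error(map_flank(paste0("ACGT", seg), els$non_IRES, genome2),
               "terminal tag")
})

test_that("distance to the ORF +1 is signed positive upstream, zero at the ATG", {
  gene_plus <- data.frame(gene_id = "g", strand = "+", atg_pos = 1183L)
  expect_identical(distance_to_orf_start(list(ttaa_start = 1000L),
                                         gene_plus)$genomic, 183L)
  expect_identical(distance_to_orf_start(list(ttaa_start = 1183L),
                                         gene_plus)$genomic, 0L)
  expect_identical(distance_to_orf_start(list(ttaa_start = 1200L),
                                         gene_plus)$genomic, -17L)
  gene_minus <- data.frame(gene_id = "g", strand = "-", atg_pos = 500L)
  expect_identical(distance_to_orf_start(list(ttaa_start = 700L),
                                         gene_minus)$genomic, 200L)
  # no annotated CDS: distance undefined but call retained
  gene_nocds <- data.frame(gene_id = "g", strand = "+", atg_pos = NA_integer_)
  expect_true(is.na(distance_to_orf_start(list(ttaa_start = 1L),
                                          gene_nocds)$genomic))
})

test_that("the spliced distance counts only exonic bases", {
  toy <- toy_gene_world()
  # insertion in the intron (11..30); ATG at 35
  rec <- list(insertion_id = "x", ttaa_start = 15L, element_strand = "+")
  gi <- toy$models$genes[1, ]
  d <- distance_to_orf_start(rec, gi, toy$models)
  expect_identical(d$genomic, 20L)  # 35 - 15
  # exonic bases between 15 and 35: exon2 31..35 overlap = 5
  expect_identical(d$spliced, 5L)
})

test_that("tabulation conserves counts and resolves arms from metadata", {
  w <- tiny_world()
  recs <- map_flanks(w$flanks, w$els$non_IRES, w$gen$genome)
  calls <- call_features(recs[recs$status == "ok", ], w$gen$models)
  tab <- tabulate_insertions(calls)
  expect_identical(sum(tab$by_class$n), nrow(calls))
  expect_identical(sum(tab$by_ordinal$n),
                   sum(!is.na(calls$intron_ordinal)))
  expect_equal(sum(tab$by_class$fraction), 1)

  arms <- data.frame(scaffold = unique(calls$scaffold),
                     arm = "2R", stringsAsFactors = FALSE)
  tab2 <- tabulate_insertions(calls, arms)
  expect_identical(names(tab2$by_location)[1], "arm")
  expect_identical(sum(tab2$by_location$n), nrow(calls))

  empty <- tabulate_insertions(calls[0, ])
  expect_identical(empty$n_calls, 0L)
  expect_identical(sum(empty$by_class$n), 0L)
})
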
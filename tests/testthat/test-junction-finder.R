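test_that("marker uniqueness detects planted occurrences on either strand", {
  el <- default_trap_element("non_IRES")
  marker <- substr(el$reporter_orf, 1L, 14L)
  set.seed(77)
  bg <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")
  clean <- scrub <- c(chr = bg)
  # brute-force oracle on the background: scan every window on both strands
  windows <- substring(bg, 1:(4000 - 13), 14:4000)
  has_marker <- any(windows == marker) || any(windows == revcomp(marker))
  mu <- verify_marker_uniqueness(clean, el$reporter_orf, 14L)
  expect_identical(mu$unique, !has_marker)

  planted <- c(chr = paste0(substr(bg, 1, 2000), marker, substr(bg, 2001, 4000)))
  mu2 <- verify_marker_uniqueness(planted, el$reporter_orf, 14L)
  expect_false(mu2$unique)
  expect_identical(nrow(mu2$hits), 1L)
  expect_identical(mu2$hits$start, 2001L)

  # k = full ORF on a genome holding only a 100-nt prefix: still unique
  partial <- c(chr = paste0(bg, substr(el$reporter_orf, 1, 100)))
  mu3 <- verify_marker_uniqueness(partial, el$reporter_orf,
                                  nchar(el$reporter_orf))
  expect_true(mu3$unique)
  expect_error(verify_marker_uniqueness(c(chr = ""), el$reporter_orf), "empty")
})

test_that("acceptance flips exactly at the 14/47/15-nt thresholds", {
  el <- default_trap_element("non_IRES")
  run <- function(tag_len, rep_len, mate_len) {
    p <- engineered_pair(tag_len, rep_len, mate_len, el)
    nrow(scan_read_pairs(p$r1, p$r2, el$reporter_orf))
  }
  expect_identical(run(15L, 14L, 47L), 1L)  # minimal passing pair
  expect_identical(run(14L, 14L, 47L), 0L)  # genomic tag one short
  expect_identical(run(15L, 13L, 47L), 0L)  # reporter match one short
  expect_identical(run(15L, 14L, 46L), 0L)  # mate match one short
})

test_that("construct discrimination follows the 15-nt retained-tag rule", {
  params <- finder_params()
  tag <- params$ires_tag
  expect_identical(classify_construct(paste0("ACGTACGTACGTACGTAC", tag), params),
                   "IRES")
  expect_identical(classify_construct("ACGTACGTACGTACGTAC", params), "non_IRES")
  # junction reads starting inside the retained tag cannot be resolved
  for (len in 1:14) {
    expect_identical(
      classify_construct(substr(tag, 15L - len + 1L, 15L), params),
      "unresolved")
  }
  # scan-level: IRES pairs classified IRES, tags excised before length check
  el <- default_trap_element("IRES")
  p <- engineered_pair(15L, 14L, 47L, el, insert = el$ires_tag)
  hits <- scan_read_pairs(p$r1, p$r2, el$reporter_orf,
                          finder_params(ires_tag = el$ires_tag))
  expect_identical(hits$construct, "IRES")
  expect_identical(nchar(hits$genomic_tag), 15L)
})

test_that("pair geometry is enforced: the reporter segment must run toward its mate", {
  el <- default_trap_element("non_IRES")
  good <- engineered_pair(20L, 20L, 50L, el)
  bad <- engineered_pair(20L, 20L, 50L, el, flip_mate = FALSE)
  expect_identical(nrow(scan_read_pairs(good$r1, good$r2, el$reporter_orf)), 1L)
  expect_identical(nrow(scan_read_pairs(bad$r1, bad$r2, el$reporter_orf)), 0L)
  relaxed <- finder_params(require_orientation = FALSE)
  expect_identical(nrow(scan_read_pairs(bad$r1, bad$r2, el$reporter_orf,
                                        relaxed)), 1L)
  expect_error(scan_read_pairs(c(a = "ACGT"), c(b = "ACGT"), el$reporter_orf),
               "ids must match")
})

test_that("scan recovers the planted chimeras exactly, with zero false positives", {
  w <- tiny_world()
  hits <- scan_read_pairs(w$r1, w$r2, w$els$non_IRES$reporter_orf)
  truth_ids <- chimeric_ids(w$truth)
  expect_setequal(hits$pair_id, truth_ids)
  # construct counts equal planted per-construct chimera counts
  per_construct <- vapply(split(w$truth, w$truth$construct),
                          function(d) length(chimeric_ids(d)), integer(1))
  expect_identical(as.integer(table(hits$construct)[names(per_construct)]),
                   unname(per_construct))
})

test_that("raising any threshold never increases the hit count", {
  w <- tiny_world()
  sub_ids <- unique(c(chimeric_ids(w$truth), names(w$r1)[1:60]))
  r1 <- w$r1[sub_ids]; r2 <- w$r2[sub_ids]
  rep_orf <- w$els$non_IRES$reporter_orf
  counts <- array(NA_integer_, dim = c(3, 2, 3))
  reps <- c(14L, 20L, 30L); mates <- c(47L, 50L); tags <- c(15L, 18L, 21L)
  for (i in seq_along(reps)) for (j in seq_along(mates)) for (k in seq_along(tags)) {
    counts[i, j, k] <- nrow(scan_read_pairs(
      r1, r2, rep_orf,
      finder_params(min_reporter_match = reps[i], min_mate_match = mates[j],
                    min_genomic_tag = tags[k])))
  }
  expect_true(all(apply(counts, c(2, 3), diff) <= 0))
  expect_true(all(apply(counts, c(1, 3), diff) <= 0))
  expect_true(all(apply(counts, c(1, 2), diff) <= 0))
})

test_that("the hit set is invariant under strand flip and mate swap", {
  w <- tiny_world()
  sub_ids <- unique(c(chimeric_ids(w$truth), names(w$r1)[1:40]))
  rep_orf <- w$els$non_IRES$reporter_orf
  a <- scan_read_pairs(w$r1[sub_ids], w$r2[sub_ids], rep_orf)
  flipped1 <- revcomp(w$r2[sub_ids]); names(flipped1) <- sub_ids
  flipped2 <- revcomp(w$r1[sub_ids]); names(flipped2) <- sub_ids
  b <- scan_read_pairs(flipped1, flipped2, rep_orf)
  expect_setequal(a$pair_id, b$pair_id)
})

test_that("junction localisation maps tags uniquely and labels the insertion intron", {
  w <- tiny_world()
  hits <- scan_read_pairs(w$r1, w$r2, w$els$non_IRES$reporter_orf)
  loc <- locate_junction(hits, w$gen$genome, w$gen$models)
  expect_true(all(loc$multiplicity == 1L))
  expect_true(all(loc$acceptor_dinucleotide == "AG"))
  expect_true(all(loc$acceptor_canonical))

  # every located junction belongs to the host gene of a planted insertion
  id_of <- function(pid) {
    hit <- w$truth[vapply(strsplit(w$truth$chimeric_read_ids, ","),
                          function(x) pid %in% x, logical(1)), ]
    hit$true_gene_id
  }
  for (i in seq_len(nrow(loc))) {
    expect_identical(loc$gene_id[i], id_of(loc$pair_id[i]))
  }
  # intronic labels carry the ordinal series; UTR-intron junctions say 5'-UTR
  utr_rows <- loc$feature_class == "five_prime_utr_intron"
  expect_true(all(loc$junction_location[utr_rows] == "5'-UTR"))
  expect_true(all(grepl("^Intron \\d+ of \\d+$",
                        loc$junction_location[!utr_rows])))

  # an ambiguous tag stays unmapped with its multiplicity recorded
  dup <- c(chrD = paste0(strrep("AC", 50), "GATTACAGATTACAGATTACA",
                         strrep("TG", 50), "GATTACAGATTACAGATTACA",
                         strrep("CA", 50)))
  fake <- hits[1, ]
  fake$genomic_tag <- "GATTACAGATTACAGATTACA"
  loc2 <- locate_junction(fake, dup, w$gen$models)
  expect_identical(loc2$multiplicity, 2L)
  expect_true(is.na(loc2$scaffold))
  expect_identical(nrow(aggregate_junctions(loc2)), 0L)
})

test_that("aggregation groups hits by locus and construct with conserved totals", {
  w <- tiny_world()
  hits <- scan_read_pairs(w$r1, w$r2, w$els$non_IRES$reporter_orf)
  loc <- locate_junction(hits, w$gen$genome, w$gen$models)
  tab <- aggregate_junctions(loc)
  expect_identical(sum(tab$occurrences), nrow(loc))
  expect_false(any(duplicated(paste(tab$scaffold, tab$position, tab$construct))))
})
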
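test_that("acceptor windows are the intron-terminal suffixes, AG-terminal", {
  toy <- toy_gene_world()
  w <- extract_acceptor_windows(toy$models, toy$genome, width = 7L)
  expect_identical(unname(w[1]), "TTTTCAG")
  expect_identical(attr(w, "n_skipped"), 0L)
  # intron (20 nt) shorter than a 21-nt window: skipped and counted
  w2 <- extract_acceptor_windows(toy$models, toy$genome, width = 21L)
  expect_identical(length(w2), 0L)
  expect_identical(attr(w2, "n_skipped"), 1L)
  expect_error(extract_acceptor_windows(toy$models, toy$genome, width = 1L),
               "at least 2")

  ws <- tiny_world()
  win <- extract_acceptor_windows(ws$gen$models, ws$gen$genome)
  n_introns <- sum(vapply(ws$gen$models$genes$gene_id, function(g)
    nrow(gene_introns(ws$gen$models, g)), integer(1)))
  expect_identical(length(win) + attr(win, "n_skipped"), n_introns)
  expect_true(all(substr(win, 20L, 21L) == "AG"))
})

test_that("the toy 3-mer matrix matches exhaustive enumeration", {
  m <- build_acceptor_matrix(c("AAG", "CAG", "GAG", "TAG"), pseudocount = 0)
  expect_equal(unname(m$info_content), c(0, 2, 2))
  expect_equal(m$max_score, 4)  # 0*0.25 + 2*1 + 2*1

  # brute-force oracle over all 64 3-mers with the direct formula
  bases <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(bases, bases, bases, stringsAsFactors = FALSE),
                1, paste, collapse = "")
  oracle <- vapply(all3, function(s) {
    b <- strsplit(s, "")[[1]]
    sum(m$info_content * m$freqs[cbind(match(b, bases), 1:3)])
  }, numeric(1))
  got <- vapply(all3, function(s) score_acceptor(m, s), numeric(1))
  expect_equal(got, oracle)
  expect_true(all(got <= m$max_score + 1e-12))
  expect_equal(max(got), m$max_score)
  expect_equal(score_acceptor(m, m$consensus), m$max_score)
  # consensus-indicator mode: consensus scores the full IC total
  expect_equal(score_acceptor(m, m$consensus, mode = "consensus"),
               sum(m$info_content))
})

test_that("information content spans [0, 2] with the stated edge cases", {
  ident <- build_acceptor_matrix(rep("ACGTT", 10), pseudocount = 0)
  expect_equal(unname(ident$info_content), rep(2, 5))
  unif <- build_acceptor_matrix(c("A", "C", "G", "T"), pseudocount = 0)
  expect_equal(unname(unif$info_content), 0)
  expect_equal(score_acceptor(unif, "A"), 0)  # all-zero IC scores 0
  expect_error(build_acceptor_matrix(c("AA", "ACG")), "mixed widths")
  expect_error(build_acceptor_matrix(character(0)), "at least one")
  expect_error(score_acceptor(ident, "ACGNT"), "non-ACGT.*N")
  expect_error(score_acceptor(ident, "ACGTTT"), "longer than")
})

test_that("shorter sequences are right-aligned to the acceptor end", {
  w <- tiny_world()
  win <- extract_acceptor_windows(w$gen$models, w$gen$genome)
  m <- build_acceptor_matrix(win)
  planned <- "TTCCCCCCTCCCAGCAG"  # 17 nt vs width 21
  got <- score_acceptor(m, planned)
  b <- strsplit(planned, "")[[1]]
  pos <- 5:21
  manual <- sum(m$info_content[pos] *
                  m$freqs[cbind(match(b, c("A", "C", "G", "T")), pos)])
  expect_equal(got, manual)
  expect_lte(got, m$max_score)
})

test_that("increasing the pseudocount never increases positional information", {
  set.seed(99)
  for (rep in 1:5) {
    win <- vapply(1:12, function(i)
      paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE,
                   prob = c(0.5, 0.2, 0.2, 0.1)), collapse = ""), character(1))
    ics <- sapply(c(0, 0.5, 1, 2, 5), function(pc)
      build_acceptor_matrix(win, pseudocount = pc)$info_content)
    expect_true(all(apply(ics, 1, diff) <= 1e-12))
  }
})

test_that("true acceptors outscore random genomic 21-mers and the matrix round-trips", {
  w <- tiny_world()
  win <- extract_acceptor_windows(w$gen$models, w$gen$genome)
  m <- build_acceptor_matrix(win)
  set.seed(123)
  sc <- w$gen$genome[[1]]
  starts <- sample.int(nchar(sc) - 21L, 300)
  rand <- substring(sc, starts, starts + 20L)
  rand_scores <- vapply(rand, function(s) score_acceptor(m, s), numeric(1))
  acc_scores <- vapply(win, function(s) score_acceptor(m, s), numeric(1))
  expect_gt(mean(acc_scores), mean(rand_scores))
  expect_true(all(c(acc_scores, rand_scores) <= m$max_score + 1e-12))

  tsv <- tempfile(fileext = ".tsv")
  write_acceptor_matrix(m, tsv)
  m2 <- read_acceptor_matrix(tsv)
  unlink(tsv)
  expect_equal(m2$freqs, m$freqs, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m2$info_content, m$info_content, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m2$max_score, m$max_score, tolerance = 1e-9)
  expect_identical(m2$consensus, m$consensus)
})
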
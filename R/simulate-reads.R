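#' Fusion transcript of a reporting insertion
#'
#' Builds the chimeric mRNA produced when a promoter-trap element inserted
#' in an intron, on the same strand as the host transcript, is spliced into
#' the message: host exons 5' of the insertion intron, then the element
#' exonic part. For the non-IRES construct the host exon fuses directly to
#' the reporter +1 (planned splice acceptor); for the IRES construct the
#' splice uses the unplanned acceptor 15 nt upstream of the reporter +1, so
#' the retained 15-nt element tag precedes the reporter.
#'
#' Insertions on the opposite strand, or outside introns, cannot report and
#' are refused.
#'
#' @param models `gene_models`.
#' @param genome named character vector of scaffolds (unmodified).
#' @param ins one row of the truth table from [plant_insertions()].
#' @param element the [trap_element()] matching `ins$construct`.
#' @return list with `seq` (fusion mRNA), `fusion_point` (last host base,
#'   1-based in `seq`; for IRES the retained tag follows it),
#'   `reporter_start` (position of the reporter +1 in `seq`), and
#'   `donor_exon_len` (length of the host exon immediately 5' of the
#'   junction).
#' @export
fusion_transcript <- function(models, genome, ins, element) {
  genome <- as_genome_vector(genome)
  if (is.na(ins$orientation) || ins$orientation != "same_strand") {
    stop("non-reporting orientation: fusion transcripts require a ",
         "same-strand insertion")
  }
  if (!ins$true_feature_class %in% c("five_prime_utr_intron", "coding_intron")) {
    stop("non-reporting insertion: fusion transcripts require an intronic ",
         "insertion (got '", ins$true_feature_class, "')")
  }
  gi <- models$genes[models$genes$gene_id == ins$true_gene_id, ]
  ints <- gene_introns(models, ins$true_gene_id)
  ord <- ins$true_intron_ordinal
  ex <- models$features[models$features$gene_id == ins$true_gene_id &
                          models$features$type == "exon", ]
  ex <- ex[order(ex$start), ]
  if (gi$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  # exons 1..ord (transcript order) lie 5' of intron `ord`
  up <- ex[seq_len(ord), , drop = FALSE]
  parts <- substring(genome[[gi$scaffold]], up$start, up$end)
  host <- paste(if (gi$strand == "-") revcomp(parts) else parts, collapse = "")

  if (element$construct == "IRES") {
    tag <- element$ires_tag
  } else {
    tag <- ""
  }
  seq <- paste0(host, tag, element$reporter_orf, element$tail_spacer)
  list(seq = seq,
       fusion_point = nchar(host),
       reporter_start = nchar(host) + nchar(tag) + 1L,
       reporter_len = nchar(element$reporter_orf),
       donor_exon_len = up$end[nrow(up)] - up$start[nrow(up)] + 1L)
}

#' Simulate paired-end transcript reads with reporter-fusion chimeras
#'
#' Emits `n_read_pairs` 50-nt (configurable) read pairs: background pairs
#' drawn uniformly from spliced transcript sequence (polyA selection
#' approximated as transcript-only reads), plus
#' `round(chimera_fraction * n_read_pairs)` fusion pairs from reporting
#' insertions (same-strand, intronic). Each fusion pair has one mate fully
#' inside the reporter ORF and one junction-spanning mate whose 5' part is a
#' host-exon tag of at least 15 nt and whose 3' part is the reporter +1
#' prefix (non-IRES) or the 15-nt retained element tag plus the reporter +1
#' prefix (IRES). Junction mates are oriented toward their mate (standard
#' forward-reverse pair geometry); which file a mate lands in is random.
#'
#' The genome must already be free of the reporter marker k-mer (guaranteed
#' by [generate_genome()]'s scrubbing), which [verify_marker_uniqueness()]
#' can assert.
#'
#' @param gen a `trap_genome`.
#' @param truth truth table from [plant_insertions()].
#' @param elements named list of [trap_element()]s keyed by construct.
#' @param config a [synthetic_config()] (defaults to `gen$config`).
#' @return list with `r1`, `r2` (named character vectors of read
#'   sequences; names are shared pair ids) and `truth` updated with
#'   comma-separated `chimeric_read_ids`.
#' @export
simulate_reads <- function(gen, truth, elements = default_elements(),
                           config = gen$config) {
  stopifnot(inherits(gen, "trap_genome"))
  models <- gen$models
  genome <- gen$genome
  rl <- config$read_length
  n_pairs <- config$n_read_pairs
  n_chim <- as.integer(round(config$chimera_fraction * n_pairs))

  reporting <- which(!is.na(truth$orientation) &
                       truth$orientation == "same_strand" &
                       truth$true_feature_class %in%
                         c("five_prime_utr_intron", "coding_intron"))
  if (n_chim > 0L && !length(reporting)) {
    stop("no reporting (same-strand intronic) insertion available for chimeras")
  }

  with_seed(derive_seed(config$seed, 2), {
    tx_seqs <- vapply(models$genes$gene_id, function(g)
      transcript_sequence(models, genome, g), character(1))
    tx_seqs <- tx_seqs[nchar(tx_seqs) >= 2L * rl + 20L]

    fusions <- lapply(reporting, function(i)
      fusion_transcript(models, genome, truth[i, ],
                        elements[[truth$construct[i]]]))

    r1 <- character(n_pairs); r2 <- character(n_pairs)
    ids <- sprintf("pair%06d", seq_len(n_pairs))
    chim_slots <- if (n_chim > 0L) sort(sample.int(n_pairs, n_chim)) else integer(0)
    chim_owner <- if (n_chim > 0L) {
      reporting[1L + (seq_len(n_chim) - 1L) %% length(reporting)]
    } else integer(0)
    chim_ids <- stats::setNames(vector("list", nrow(truth)), truth$insertion_id)

    ci <- 0L
    for (p in seq_len(n_pairs)) {
      if (p %in% chim_slots) {
        ci <- ci + 1L
        own <- chim_owner[ci]
        fu <- fusions[[match(own, reporting)]]
        pr <- chimeric_pair(fu, truth$construct[own], rl)
        chim_ids[[truth$insertion_id[own]]] <-
          c(chim_ids[[truth$insertion_id[own]]], ids[p])
      } else {
        pr <- background_pair(tx_seqs, rl)
      }
      if (stats::runif(1) < 0.5) pr <- rev(pr)
      r1[p] <- pr[1L]; r2[p] <- pr[2L]
    }

    if (config$error_rate > 0) {
      r1 <- add_errors(r1, config$error_rate)
      r2 <- add_errors(r2, config$error_rate)
    }
    names(r1) <- ids; names(r2) <- ids
    truth$chimeric_read_ids <- vapply(truth$insertion_id, function(id)
      paste(chim_ids[[id]], collapse = ","), character(1))
    list(r1 = r1, r2 = r2, truth = truth)
  })
}

# One chimeric pair: junction-spanning read + mate fully in the reporter.
chimeric_pair <- function(fu, construct, rl) {
  tag_extra <- if (construct == "IRES") 15L else 0L
  min_tag <- 15L; min_rep <- 14L
  max_tag <- min(rl - min_rep - tag_extra, fu$donor_exon_len)
  t_len <- rint(1L, min_tag, max(min_tag, max_tag))
  start <- fu$fusion_point - t_len + 1L
  junction_read <- substr(fu$seq, start, start + rl - 1L)

  rep_lo <- fu$reporter_start
  rep_hi <- fu$reporter_start + fu$reporter_len - rl  # mate fully in reporter
  m_lo <- max(rep_lo, start + 1L)
  m_start <- rint(1L, m_lo, max(m_lo, min(rep_hi, m_lo + 250L)))
  mate <- revcomp(substr(fu$seq, m_start, m_start + rl - 1L))
  c(junction_read, mate)
}

# One background pair from a random spliced transcript.
background_pair <- function(tx_seqs, rl) {
  tx <- tx_seqs[[rint(1L, 1L, length(tx_seqs))]]
  frag_len <- rint(1L, 2L * rl + 10L, min(nchar(tx), 300L))
  start <- rint(1L, 1L, nchar(tx) - frag_len + 1L)
  frag <- substr(tx, start, start + frag_len - 1L)
  c(substr(frag, 1L, rl),
    revcomp(substr(frag, frag_len - rl + 1L, frag_len)))
}

add_errors <- function(reads, rate) {
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(stats::runif(n) < rate)
    for (p in hit) {
      b <- substr(r, p, p)
      substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }
    r
  }, character(1), USE.NAMES = FALSE)
}
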
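#' Parameters for exact-match fusion-read classification
#'
#' The classifier accepts a read pair as a reporter-fusion event iff
#' (1) one mate carries an exact match of at least `min_reporter_match` nt
#' to the reporter ORF anchored at its +1, occupying the 3' end of that
#' read once oriented to the reporter strand; (2) that reporter segment
#' runs toward the other mate; (3) the other mate is an exact substring of
#' the reporter of at least `min_mate_match` nt; and (4) the junction
#' mate's non-reporter 5' segment, after excision of a full 15-nt IRES
#' retained tag when present, is a genomic tag of at least
#' `min_genomic_tag` nt. Defaults are the screen's published thresholds:
#' 14 / 47 / 15 nt.
#'
#' @param min_reporter_match minimum reporter +1 prefix match (nt).
#' @param min_mate_match minimum exact reporter match in the mate (nt).
#' @param min_genomic_tag minimum genomic tag length (nt).
#' @param ires_tag the 15-nt element tag retained 5' of the reporter +1 in
#'   IRES-construct fusions.
#' @param require_orientation enforce pair geometry (reporter segment of
#'   the junction mate oriented toward its mate). Default on.
#' @param planned_sa_context,unplanned_sa_context element acceptor windows
#'   (used to report the acceptor dinucleotide of located junctions).
#' @return object of class `finder_params`.
#' @export
finder_params <- function(min_reporter_match = 14L,
                          min_mate_match = 47L,
                          min_genomic_tag = 15L,
                          ires_tag = default_trap_element("IRES")$ires_tag,
                          require_orientation = TRUE,
                          planned_sa_context = default_trap_element("non_IRES")$planned_sa_context,
                          unplanned_sa_context = default_trap_element("IRES")$unplanned_sa_context) {
  stopifnot(min_reporter_match >= 1L, min_mate_match >= 1L,
            min_genomic_tag >= 1L)
  if (nchar(ires_tag) != 15L) stop("ires_tag must be exactly 15 nt")
  structure(list(
    min_reporter_match = as.integer(min_reporter_match),
    min_mate_match = as.integer(min_mate_match),
    min_genomic_tag = as.integer(min_genomic_tag),
    ires_tag = ires_tag,
    require_orientation = isTRUE(require_orientation),
    planned_sa_context = planned_sa_context,
    unplanned_sa_context = unplanned_sa_context
  ), class = "finder_params")
}

#' Verify reporter marker uniqueness in a genome
#'
#' Checks that the first `k` nt of the reporter ORF occur nowhere in the
#' genome, on either strand. When true, every read carrying that k-mer must
#' derive from a fusion transcript, so exact-match junction detection has a
#' zero false-positive guarantee at error rate 0.
#'
#' @param genome named character vector, `DNAStringSet` or `trap_genome`.
#' @param reporter_orf reporter ORF sequence.
#' @param k marker length (default 14).
#' @return list with `unique` (logical) and `hits` (data.frame of
#'   violations: scaffold, start, end, strand).
#' @export
verify_marker_uniqueness <- function(genome, reporter_orf, k = 14L) {
  genome <- as_genome_vector(genome)
  if (!length(genome) || all(!nchar(genome))) stop("empty genome")
  if (k > nchar(reporter_orf)) stop("k exceeds reporter length")
  marker <- substr(reporter_orf, 1L, k)
  hits <- match_genome(marker, genome)
  list(unique = nrow(hits) == 0L, hits = hits)
}

# Longest reporter +1 prefix occupying the 3' end of `read`; 0 if none or
# below `min_len`.
suffix_anchored_prefix <- function(read, reporter, min_len) {
  L <- nchar(read)
  top <- min(L, nchar(reporter))
  if (top < min_len) return(0L)
  for (len in seq.int(top, min_len, by = -1L)) {
    if (substr(read, L - len + 1L, L) == substr(reporter, 1L, len)) return(len)
  }
  0L
}

# TRUE iff `read` contains an exact, contiguous >= min_len match to the
# reporter.
mate_matches_reporter <- function(read, reporter, min_len) {
  L <- nchar(read)
  if (L < min_len) return(FALSE)
  if (grepl(read, reporter, fixed = TRUE)) return(TRUE)
  for (off in 0:(L - min_len)) {
    if (grepl(substr(read, off + 1L, off + min_len), reporter, fixed = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Scan paired-end reads for reporter-fusion junctions
#'
#' Applies the exact-match acceptance rules of [finder_params()] to every
#' read pair, searching both mates and both orientations. Pairs failing any
#' rule are silently skipped.
#'
#' @param r1,r2 named character vectors of read sequences (see
#'   [read_fastq()]) with identical ids in identical order, or FASTQ paths.
#' @param reporter_orf reporter ORF sequence.
#' @param params a [finder_params()].
#' @return data.frame of junction hits: `pair_id`, `junction_read`
#'   (`"R1"`/`"R2"`), `junction_strand` (orientation in which the junction
#'   mate matched the reporter sense), `reporter_match_len`, `construct`
#'   (`non_IRES`/`IRES`/`unresolved`), `genomic_tag`,
#'   `junction_seq_context` (up to 21 nt of fusion-transcript sequence
#'   ending at the reporter +1).
#' @export
scan_read_pairs <- function(r1, r2, reporter_orf, params = finder_params()) {
  if (is.character(r1) && length(r1) == 1L && file.exists(r1)) r1 <- read_fastq(r1)
  if (is.character(r2) && length(r2) == 1L && file.exists(r2)) r2 <- read_fastq(r2)
  if (length(r1) != length(r2) || !identical(names(r1), names(r2))) {
    stop("paired FASTQs disagree: read ids must match in order")
  }
  hits <- vector("list", length(r1))
  for (i in seq_along(r1)) {
    pair <- c(r1[[i]], r2[[i]])
    hit <- NULL
    for (m in 1:2) {
      for (ori in c("+", "-")) {
        jr <- if (ori == "+") pair[m] else revcomp(pair[m])
        len <- suffix_anchored_prefix(jr, reporter_orf, params$min_reporter_match)
        if (len == 0L) next
        other <- pair[3L - m]
        if (params$require_orientation) {
          # FR geometry: junction mate on the fusion-transcript sense means
          # its mate reads the antisense, and vice versa.
          mate_ok <- mate_matches_reporter(
            if (ori == "+") revcomp(other) else other,
            reporter_orf, params$min_mate_match)
        } else {
          mate_ok <- mate_matches_reporter(other, reporter_orf,
                                           params$min_mate_match) ||
            mate_matches_reporter(revcomp(other), reporter_orf,
                                  params$min_mate_match)
        }
        if (!mate_ok) next
        part <- substr(jr, 1L, nchar(jr) - len)
        cls <- classify_construct(part, params)
        gtag <- if (cls == "IRES") {
          substr(part, 1L, nchar(part) - 15L)
        } else if (cls == "non_IRES") {
          part
        } else {
          ""
        }
        if (nchar(gtag) < params$min_genomic_tag) next
        ctx_from <- max(1L, nchar(part) - 20L)
        hit <- data.frame(
          pair_id = names(r1)[i],
          junction_read = c("R1", "R2")[m],
          junction_strand = ori,
          reporter_match_len = len,
          construct = cls,
          genomic_tag = gtag,
          junction_seq_context = substr(part, ctx_from, nchar(part)),
          stringsAsFactors = FALSE)
        break
      }
      if (!is.null(hit)) break
    }
    hits[[i]] <- hit
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(pair_id = character(0), junction_read = character(0),
                      junction_strand = character(0),
                      reporter_match_len = integer(0), construct = character(0),
                      genomic_tag = character(0),
                      junction_seq_context = character(0)))
  }
  do.call(rbind, hits)
}

#' Classify the construct of a junction read
#'
#' Applies the 15-nt discrimination rule to the junction mate's sequence 5'
#' of the reporter +1: `IRES` iff the full 15-nt retained element tag abuts
#' the reporter +1; `unresolved` when the read starts inside that tag
#' (fewer than 15 tag nt visible, so the construct cannot be decided);
#' `non_IRES` otherwise (genomic sequence abuts the +1 directly, the
#' planned-acceptor junction).
#'
#' @param junction_prefix sequence of the junction mate 5' of the reporter
#'   +1 (reporter-sense orientation).
#' @param params a [finder_params()].
#' @return one of `"non_IRES"`, `"IRES"`, `"unresolved"`.
#' @export
classify_construct <- function(junction_prefix, params = finder_params()) {
  tag <- params$ires_tag
  n <- nchar(junction_prefix)
  if (n >= 15L && substr(junction_prefix, n - 14L, n) == tag) return("IRES")
  if (n > 0L && n < 15L &&
      junction_prefix == substr(tag, 15L - n + 1L, 15L)) {
    return("unresolved")
  }
  "non_IRES"
}

#' Locate junction hits on the genome and annotate them
#'
#' Exact-matches each hit's genomic tag against both strands of the genome.
#' A unique match is reported as a locus whose position is the
#' fusion-proximal (3') end of the tag -- the host exon base joined to the
#' element splice acceptor; multi-mapping tags are left unmapped with their
#' multiplicity recorded and are excluded from downstream aggregation. When
#' the locus coincides with an annotated splice donor, the junction is
#' labelled by the intron the element inserted into: `5'-UTR` for 5'-UTR
#' introns, otherwise `Intron i of n` (one ordinal series over UTR and
#' coding introns); other loci are labelled by their own feature. The
#' acceptor dinucleotide is the last 2 nt of the element acceptor that
#' formed the junction.
#'
#' @param hits data.frame from [scan_read_pairs()].
#' @param genome named character vector, `DNAStringSet` or `trap_genome`.
#' @param models `gene_models` annotation.
#' @param params a [finder_params()].
#' @return `hits` with added columns `scaffold`, `position`, `strand`,
#'   `multiplicity`, `gene_id`, `junction_location`, `feature_class`,
#'   `acceptor_dinucleotide`, `acceptor_canonical`.
#' @export
locate_junction <- function(hits, genome, models, params = finder_params()) {
  genome <- as_genome_vector(genome)
  n <- nrow(hits)
  add <- data.frame(scaffold = rep(NA_character_, n), position = NA_integer_,
                    strand = NA_character_, multiplicity = 0L,
                    gene_id = NA_character_,
                    junction_location = NA_character_,
                    feature_class = NA_character_,
                    acceptor_dinucleotide = NA_character_,
                    acceptor_canonical = NA, stringsAsFactors = FALSE)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    tag <- hits$genomic_tag[i]
    if (nchar(tag) < params$min_genomic_tag) {
      stop("genomic tag shorter than min_genomic_tag in hit ", hits$pair_id[i])
    }
    m <- if (!is.null(cache[[tag]])) cache[[tag]] else {
      cache[[tag]] <- match_genome(tag, genome)
      cache[[tag]]
    }
    add$multiplicity[i] <- nrow(m)
    ctx <- if (hits$construct[i] == "IRES") {
      params$unplanned_sa_context
    } else {
      params$planned_sa_context
    }
    add$acceptor_dinucleotide[i] <- substr(ctx, nchar(ctx) - 1L, nchar(ctx))
    add$acceptor_canonical[i] <- add$acceptor_dinucleotide[i] == "AG"
    if (nrow(m) != 1L) next
    add$scaffold[i] <- m$scaffold
    add$strand[i] <- m$strand
    # fusion-proximal end of the tag: 3' end in transcript sense
    add$position[i] <- if (m$strand == "+") m$end else m$start
    lab <- junction_label(models, m$scaffold, add$position[i], m$strand)
    add$gene_id[i] <- lab$gene_id
    add$junction_location[i] <- lab$label
    add$feature_class[i] <- lab$feature_class
  }
  cbind(hits, add)
}

# Label a junction locus: the intron following a splice donor when the
# locus sits exactly at an exon 3' boundary, else the containing feature.
junction_label <- function(models, scaffold, position, strand) {
  g <- models$genes
  cand <- g[g$scaffold == scaffold & g$start <= position & g$end >= position &
              g$strand == strand, ]
  if (!nrow(cand)) {
    return(list(gene_id = NA_character_, label = "intergenic",
                feature_class = "intergenic"))
  }
  gi <- cand[1L, ]
  ints <- gene_introns(models, gi$gene_id)
  follow <- if (strand == "+") {
    which(ints$start == position + 1L)
  } else {
    which(ints$end == position - 1L)
  }
  if (length(follow) == 1L) {
    lab <- if (ints$is_utr[follow]) {
      "5'-UTR"
    } else {
      sprintf("Intron %d of %d", ints$ordinal[follow], ints$n_introns[follow])
    }
    cls <- if (ints$is_utr[follow]) "five_prime_utr_intron" else "coding_intron"
    return(list(gene_id = gi$gene_id, label = lab, feature_class = cls))
  }
  fx <- models$features[models$features$gene_id == gi$gene_id, ]
  ov <- fx[fx$start <= position & fx$end >= position, ]
  if (any(ov$type == "three_prime_UTR")) {
    list(gene_id = gi$gene_id, label = "3'-UTR", feature_class = "three_prime_utr")
  } else if (any(ov$type == "exon")) {
    list(gene_id = gi$gene_id, label = "exon", feature_class = "exon")
  } else {
    ik <- which(ints$start <= position & ints$end >= position)
    if (length(ik) == 1L) {
      lab <- if (ints$is_utr[ik]) "5'-UTR" else {
        sprintf("Intron %d of %d", ints$ordinal[ik], ints$n_introns[ik])
      }
      cls <- if (ints$is_utr[ik]) "five_prime_utr_intron" else "coding_intron"
      list(gene_id = gi$gene_id, label = lab, feature_class = cls)
    } else {
      list(gene_id = gi$gene_id, label = "gene", feature_class = "exon")
    }
  }
}

#' Aggregate junction hits into an occurrence table
#'
#' Groups located hits by (scaffold, position, construct) and reports
#' occurrence counts with the gene and junction location -- the screen's
#' resolvable-splicing-events table. Unmapped and multi-mapping hits are
#' excluded (multiplicity != 1).
#'
#' @param located data.frame from [locate_junction()].
#' @return data.frame with `construct`, `gene_id`, `occurrences`,
#'   `scaffold`, `position`, `junction_location`, sorted by construct and
#'   gene.
#' @export
aggregate_junctions <- function(located) {
  ok <- located[located$multiplicity == 1L, , drop = FALSE]
  if (!nrow(ok)) {
    return(data.frame(construct = character(0), gene_id = character(0),
                      occurrences = integer(0), scaffold = character(0),
                      position = integer(0), junction_location = character(0)))
  }
  key <- paste(ok$scaffold, ok$position, ok$construct)
  agg <- lapply(split(ok, key), function(d) {
    data.frame(construct = d$construct[1L], gene_id = d$gene_id[1L],
               occurrences = nrow(d), scaffold = d$scaffold[1L],
               position = d$position[1L],
               junction_location = d$junction_location[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$construct, out$gene_id, out$position), ]
  rownames(out) <- NULL
  out
}
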
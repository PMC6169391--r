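#' Map one splinkerette flank to an insertion site
#'
#' A flank must begin with a recognizable element terminal tag (at least 20
#' nt exact match to the outward reading of either piggyBac terminus). The
#' tag is stripped, the remaining genomic portion is exact-matched against
#' both strands of the genome, a unique hit is required, the TTAA target
#' site is verified at the element-genome junction, and the element's
#' genomic orientation is inferred from which terminus was present and the
#' matched strand.
#'
#' @param flank one row of the [simulate_splinkerette()] table, or a single
#'   flank sequence string.
#' @param element a [trap_element()] (termini are shared between
#'   constructs, so either element works).
#' @param genome named character vector, `DNAStringSet` or `trap_genome`.
#' @param construct construct label to carry through (taken from the flank
#'   row when given a row).
#' @param insertion_id id to carry through (likewise).
#' @return one-row data.frame (an insertion record): `insertion_id`,
#'   `scaffold`, `ttaa_start` (1-based), `element_strand`, `construct`,
#'   `side`, `junction_ttaa_ok`.
#' @export
map_flank <- function(flank, element = default_trap_element("non_IRES"),
                      genome, construct = NA_character_,
                      insertion_id = NA_character_) {
  if (is.data.frame(flank)) {
    construct <- flank$construct %||% construct
    insertion_id <- flank$insertion_id %||% insertion_id
    flank <- flank$flank_sequence
  }
  genome <- as_genome_vector(genome)
  eseq <- element_sequence(element)
  tag5 <- revcomp(substr(eseq, 1L, 30L))
  tag3 <- substr(eseq, nchar(eseq) - 29L, nchar(eseq))

  head20 <- substr(flank, 1L, 20L)
  side <- if (head20 == substr(tag5, 1L, 20L)) {
    "5p"
  } else if (head20 == substr(tag3, 1L, 20L)) {
    "3p"
  } else {
    stop("flank does not begin with a piggyBac terminal tag (>= 20 nt)")
  }
  # strip the full element tag: longest prefix shared with the 30-nt tag
  tag <- if (side == "5p") tag5 else tag3
  taglen <- 20L
  while (taglen < 30L &&
         substr(flank, taglen + 1L, taglen + 1L) == substr(tag, taglen + 1L, taglen + 1L)) {
    taglen <- taglen + 1L
  }
  gpart <- substr(flank, taglen + 1L, nchar(flank))
  if (nchar(gpart) < 14L) stop("flank genomic portion too short to map")

  m <- match_genome(gpart, genome)
  if (nrow(m) == 0L) stop("flank genomic portion has no genomic match")
  if (nrow(m) > 1L) {
    stop(sprintf("ambiguous flank: genomic portion matches %d loci", nrow(m)))
  }
  # The element-proximal end of the genomic match carries the TTAA:
  # a minus-strand match puts it at the match end, a plus-strand match at
  # the match start. Element orientation follows from terminus + strand.
  if (m$strand == "-") {
    ttaa_start <- m$end - 3L
    element_strand <- if (side == "5p") "+" else "-"
  } else {
    ttaa_start <- m$start
    element_strand <- if (side == "5p") "-" else "+"
  }
  junction <- substr(genome[[m$scaffold]], ttaa_start, ttaa_start + 3L)
  ok <- junction == "TTAA"
  if (!ok) {
    warning(sprintf("junction at %s:%d is %s, not TTAA; record flagged",
                    m$scaffold, ttaa_start, junction))
  }
  data.frame(insertion_id = insertion_id, scaffold = m$scaffold,
             ttaa_start = ttaa_start, element_strand = element_strand,
             construct = construct, side = side, junction_ttaa_ok = ok,
             stringsAsFactors = FALSE)
}

#' Map a whole table of splinkerette flanks
#'
#' Batch wrapper around [map_flank()]: failures (no tag, ambiguous match,
#' unmappable) are collected per flank instead of aborting the run.
#'
#' @param flanks data.frame from [simulate_splinkerette()].
#' @param element a [trap_element()].
#' @param genome genome object.
#' @return data.frame of insertion records with a `status` column
#'   (`"ok"` or the failure message).
#' @export
map_flanks <- function(flanks, element = default_trap_element("non_IRES"),
                       genome) {
  genome <- as_genome_vector(genome)
  rows <- lapply(seq_len(nrow(flanks)), function(i) {
    rec <- tryCatch(
      suppressWarnings(map_flank(flanks[i, ], element, genome)),
      error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      data.frame(insertion_id = flanks$insertion_id[i] %||% NA_character_,
                 scaffold = NA_character_, ttaa_start = NA_integer_,
                 element_strand = NA_character_,
                 construct = flanks$construct[i] %||% NA_character_,
                 side = flanks$side[i] %||% NA_character_,
                 junction_ttaa_ok = NA, status = rec,
                 stringsAsFactors = FALSE)
    } else {
      rec$status <- "ok"
      rec
    }
  })
  do.call(rbind, rows)
}

#' Classify an insertion site against gene models
#'
#' Classifies the TTAA site (its second base as the reference point)
#' relative to the host transcript: 5'-UTR intron, coding intron (with
#' ordinal i of n counted 5' to 3' including UTR introns), exon, 3'-UTR, or
#' intergenic. When transcripts on both strands overlap the site, the
#' transcript in reporting orientation (transcript strand equal to the
#' element's sense strand) wins; failing that, the transcript whose
#' transcription start is nearer.
#'
#' @param rec insertion record from [map_flank()] (or any data.frame row
#'   with `scaffold`, `ttaa_start`, `element_strand`).
#' @param models `gene_models`.
#' @param genome optional genome for spliced-distance computation.
#' @return one-row data.frame (a feature call): `insertion_id`,
#'   `feature_class`, `gene_id`, `intron_ordinal`, `n_introns`,
#'   `reporting_orientation`, `distance_to_orf_start` (genomic bp, positive
#'   upstream of the +1 ATG), `spliced_distance_to_orf_start`.
#' @export
call_feature <- function(rec, models, genome = NULL) {
  pos <- rec$ttaa_start + 1L  # TTAA midpoint convention
  g <- models$genes
  cand <- g[g$scaffold == rec$scaffold & g$start <= pos & g$end >= pos, ]

  out <- data.frame(insertion_id = rec$insertion_id %||% NA_character_,
                    feature_class = "intergenic", gene_id = NA_character_,
                    intron_ordinal = NA_integer_, n_introns = NA_integer_,
                    reporting_orientation = NA,
                    distance_to_orf_start = NA_integer_,
                    spliced_distance_to_orf_start = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!nrow(cand)) return(out)
  if (nrow(cand) > 1L) {
    # tie-break: reporting orientation first, then nearer TSS
    rep_ok <- cand$strand == rec$element_strand
    if (any(rep_ok)) {
      cand <- cand[rep_ok, , drop = FALSE]
    }
    if (nrow(cand) > 1L) {
      tss <- ifelse(cand$strand == "+", cand$start, cand$end)
      cand <- cand[order(abs(tss - pos)), , drop = FALSE]
    }
  }
  gi <- cand[1L, ]
  out$gene_id <- gi$gene_id
  out$reporting_orientation <- gi$strand == rec$element_strand

  ints <- gene_introns(models, gi$gene_id)
  ik <- which(ints$start <= pos & ints$end >= pos)
  if (length(ik) == 1L) {
    out$feature_class <- if (ints$is_utr[ik]) "five_prime_utr_intron" else "coding_intron"
    out$intron_ordinal <- ints$ordinal[ik]
    out$n_introns <- ints$n_introns[ik]
  } else {
    fx <- models$features[models$features$gene_id == gi$gene_id, ]
    ov <- fx[fx$start <= pos & fx$end >= pos, ]
    out$feature_class <- if (any(ov$type == "three_prime_UTR")) {
      "three_prime_utr"
    } else {
      "exon"
    }
  }
  d <- distance_to_orf_start(rec, gi, models = models)
  out$distance_to_orf_start <- d$genomic
  out$spliced_distance_to_orf_start <- d$spliced
  out
}

#' Distance from an insertion to the ORF +1
#'
#' Genomic-coordinate distance from the TTAA start to the first base of the
#' start codon, signed positive upstream of the +1 ATG (0 when the TTAA
#' starts at the ATG itself). A spliced (transcript-coordinate) distance --
#' the count of exonic bases between the two points -- is reported as a
#' secondary value since insertions within introns are excised from the
#' message.
#'
#' @param rec insertion record (needs `ttaa_start`).
#' @param gene one row of `models$genes` for the host gene.
#' @param models `gene_models` (for the spliced distance).
#' @return list with `genomic` and `spliced` distances (bp); both `NA`
#'   when the gene has no annotated CDS.
#' @export
distance_to_orf_start <- function(rec, gene, models = NULL) {
  if (is.na(gene$atg_pos)) return(list(genomic = NA_integer_, spliced = NA_integer_))
  genomic <- if (gene$strand == "+") {
    gene$atg_pos - rec$ttaa_start
  } else {
    rec$ttaa_start - gene$atg_pos
  }
  spliced <- NA_integer_
  if (!is.null(models)) {
    ex <- models$features[models$features$gene_id == gene$gene_id &
                            models$features$type == "exon", ]
    lo <- min(rec$ttaa_start, gene$atg_pos)
    hi <- max(rec$ttaa_start, gene$atg_pos)
    ovl <- pmax(0L, pmin(ex$end, hi) - pmax(ex$start, lo) + 1L)
    spliced <- as.integer(sum(ovl) * sign(genomic))
  }
  list(genomic = as.integer(genomic), spliced = spliced)
}

#' Batch feature calls for a table of insertion records
#'
#' @param recs data.frame of insertion records (deduplicated by
#'   `insertion_id`: when both flanks of an insertion mapped, one call is
#'   made per insertion).
#' @param models `gene_models`.
#' @return data.frame of feature calls, one row per insertion.
#' @export
call_features <- function(recs, models) {
  recs <- recs[!is.na(recs$ttaa_start), , drop = FALSE]
  recs <- recs[!duplicated(recs$insertion_id), , drop = FALSE]
  calls <- lapply(seq_len(nrow(recs)), function(i) {
    cbind(call_feature(recs[i, ], models),
          recs[i, c("scaffold", "ttaa_start", "element_strand", "construct")])
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Tabulate insertion feature calls
#'
#' Summarises a set of feature calls the way a screen reports them: counts
#' and fractions per feature class, intronic counts by intron ordinal, and
#' counts per scaffold (or per chromosome arm when a scaffold-to-arm map is
#' supplied).
#'
#' @param calls data.frame of feature calls from [call_features()] (needs
#'   `feature_class`, `intron_ordinal`, and optionally `scaffold`).
#' @param arms optional data.frame mapping `scaffold` to `arm`.
#' @return list of data.frames: `by_class` (feature_class, n, fraction),
#'   `by_ordinal` (intron_ordinal, n), `by_location` (scaffold or arm, n),
#'   plus `n_calls`.
#' @export
tabulate_insertions <- function(calls, arms = NULL) {
  classes <- c("five_prime_utr_intron", "coding_intron", "exon",
               "three_prime_utr", "intergenic")
  n <- nrow(calls)
  by_class <- data.frame(
    feature_class = classes,
    n = vapply(classes, function(cl) sum(calls$feature_class == cl), integer(1)),
    stringsAsFactors = FALSE)
  by_class$fraction <- if (n > 0) by_class$n / n else rep(NA_real_, nrow(by_class))

  intronic <- calls[!is.na(calls$intron_ordinal), , drop = FALSE]
  if (nrow(intronic)) {
    tab <- table(factor(intronic$intron_ordinal,
                        levels = seq_len(max(intronic$intron_ordinal))))
    by_ordinal <- data.frame(intron_ordinal = as.integer(names(tab)),
                             n = as.integer(tab))
  } else {
    by_ordinal <- data.frame(intron_ordinal = integer(0), n = integer(0))
  }

  if (!is.null(calls$scaffold) && n > 0) {
    loc <- calls$scaffold
    loc_name <- "scaffold"
    if (!is.null(arms)) {
      idx <- match(loc, arms$scaffold)
      loc <- ifelse(is.na(idx), "unassigned", arms$arm[idx])
      loc_name <- "arm"
    }
    tab <- table(loc)
    by_location <- data.frame(location = names(tab), n = as.integer(tab),
                              stringsAsFactors = FALSE)
    names(by_location)[1] <- loc_name
  } else {
    by_location <- data.frame(scaffold = character(0), n = integer(0))
  }

  list(n_calls = n, by_class = by_class, by_ordinal = by_ordinal,
       by_location = by_location)
}
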
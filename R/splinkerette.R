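#' Restriction enzyme recognition motifs
#'
#' @format named character vector of IUPAC recognition sequences for the
#'   enzymes supported by the in-silico splinkerette digest.
#' @export
splinkerette_enzymes <- c(BstYI = "RGATCY", BglII = "AGATCT")

#' Recognition sites of an enzyme in a sequence
#'
#' IUPAC-aware exact matching (e.g. the R in RGATCY matches A and G). Both
#' supported recognition sequences are palindromic, so plus-strand matches
#' cover both strands.
#'
#' @param sequence DNA string to scan.
#' @param enzyme `"BstYI"` or `"BglII"`.
#' @return data.frame with `start` and `end` of each site (1-based).
#' @examples
#' restriction_sites("TTAAAGATCCGG", "BstYI")  # RGATCY matches AGATCC
#' @export
restriction_sites <- function(sequence, enzyme = c("BstYI", "BglII")) {
  enzyme <- match.arg(enzyme)
  match_positions(splinkerette_enzymes[[enzyme]], sequence, fixed = FALSE)
}

#' Simulate splinkerette PCR flanking fragments
#'
#' For every planted insertion and each element terminus (5' and 3'), emits
#' the sequence a splinkerette PCR + Sanger read would produce: the terminal
#' 30 bp of the element (sequencing-primer-proximal tag), then the TTAA
#' junction, then flanking genomic DNA out to the first recognition site of
#' the digestion enzyme (inclusive). Fragments are reported reading
#' element-to-genome; fragments whose outward reading runs on the genomic
#' minus strand are reverse-complemented accordingly. Each insertion is
#' treated as residing in its own mosquito line, so flanking DNA is the
#' unmodified genome around that single insertion.
#'
#' If no recognition site occurs before the scaffold boundary the fragment
#' is truncated at the boundary and flagged, not dropped.
#'
#' @param genome unmodified genome (named character vector or `trap_genome`).
#' @param truth truth table from [plant_insertions()].
#' @param elements named list of [trap_element()]s keyed by construct.
#' @param enzyme `"BstYI"` or `"BglII"`.
#' @return data.frame with `insertion_id`, `side` (`"5p"`/`"3p"`),
#'   `construct`, `flank_sequence`, `truncated`.
#' @export
simulate_splinkerette <- function(genome, truth, elements = default_elements(),
                                  enzyme = c("BstYI", "BglII")) {
  enzyme <- match.arg(enzyme)
  genome <- as_genome_vector(genome)

  site_cache <- lapply(genome, restriction_sites, enzyme = enzyme)

  out <- vector("list", 2L * nrow(truth))
  k <- 0L
  for (i in seq_len(nrow(truth))) {
    ins <- truth[i, ]
    el <- elements[[ins$construct]]
    eseq <- element_sequence(el)
    tag5 <- revcomp(substr(eseq, 1L, 30L))
    tag3 <- substr(eseq, nchar(eseq) - 29L, nchar(eseq))
    sc_seq <- genome[[ins$scaffold]]
    sites <- site_cache[[ins$scaffold]]
    p <- ins$ttaa_start

    # Outward reading direction on the genome for each element terminus.
    # "+" element: 5' terminus faces the left flank (read on minus strand),
    # 3' terminus faces the right flank (read on plus strand); reversed for
    # "-" elements.
    for (side in c("5p", "3p")) {
      leftward <- xor(side == "5p", ins$element_strand == "-")
      tag <- if (side == "5p") tag5 else tag3
      if (leftward) {
        cand <- sites[sites$end <= p - 1L, , drop = FALSE]
        truncated <- !nrow(cand)
        cut <- if (truncated) 1L else max(cand$start)
        gpart <- revcomp(substr(sc_seq, cut, p + 3L))
      } else {
        cand <- sites[sites$start >= p + 4L, , drop = FALSE]
        truncated <- !nrow(cand)
        cut <- if (truncated) nchar(sc_seq) else min(cand$end)
        gpart <- substr(sc_seq, p, cut)
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        insertion_id = ins$insertion_id, side = side,
        construct = ins$construct,
        flank_sequence = paste0(tag, gpart),
        truncated = truncated, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write splinkerette flanks to FASTA
#'
#' @param flanks data.frame from [simulate_splinkerette()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_flanks_fasta <- function(flanks, path) {
  seqs <- Biostrings::DNAStringSet(flanks$flank_sequence)
  names(seqs) <- paste0(flanks$insertion_id, "|", flanks$side, "|",
                        flanks$construct,
                        ifelse(flanks$truncated, "|truncated", ""))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read splinkerette flanks from FASTA
#'
#' Inverse of [write_flanks_fasta()].
#'
#' @param path FASTA path.
#' @return data.frame with the [simulate_splinkerette()] columns.
#' @export
read_flanks_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  data.frame(
    insertion_id = vapply(parts, `[`, "", 1L),
    side = vapply(parts, `[`, "", 2L),
    construct = vapply(parts, `[`, "", 3L),
    flank_sequence = unname(as.character(x)),
    truncated = vapply(parts, function(p) length(p) > 3L && p[4L] == "truncated",
                       logical(1)),
    stringsAsFactors = FALSE)
}
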
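#' Construct a promoter-trap element model
#'
#' A promoter-trap element is a piggyBac transposon carrying a promoterless
#' fluorescent reporter ORF preceded by a 3' splice acceptor (SA). The
#' element model keeps the piggyBac terminal sequences (671 bp 5' terminus,
#' 690 bp 3' terminus), the reporter ORF, the engineered ("planned") splice
#' acceptor whose AG abuts the reporter +1, and -- for the IRES construct --
#' an IRES region that carries an additional ("unplanned") splice acceptor
#' 15 nt upstream of the reporter +1. The 15 nt between that unplanned
#' acceptor and the reporter +1 (`ires_tag`) are retained in fusion
#' transcripts and discriminate the two constructs in junction reads.
#'
#' @param reporter_orf reporter open reading frame (must start with ATG).
#' @param left_terminus piggyBac 5' terminal sequence (671 bp).
#' @param right_terminus piggyBac 3' terminal sequence (690 bp).
#' @param planned_sa_context engineered 3'-SA sequence ending in AG, fused
#'   directly to the reporter +1 in the non-IRES construct.
#' @param ires_tag 15-nt sequence immediately 5' of the reporter +1 in the
#'   IRES construct (retained exonic tag), or `NULL` for no IRES.
#' @param unplanned_sa_context 21-nt acceptor window ending in AG located
#'   immediately 5' of `ires_tag` (IRES construct only).
#' @param ires_5p IRES sequence upstream of the unplanned acceptor.
#' @param marker_spacer internal element sequence between the 5' terminus
#'   and the splice acceptor (dominant marker cassette and linkers).
#' @param tail_spacer element sequence between the reporter stop and the
#'   3' terminus (terminator region).
#' @param planned_sa_offset junction offset (bp upstream of reporter +1)
#'   of the planned acceptor; 0 means the splice joins directly at +1.
#' @param unplanned_sa_offset junction offset of the unplanned acceptor;
#'   15 means a 15-nt element tag is retained 5' of the reporter.
#' @return An object of class `trap_element`.
#' @seealso [default_trap_element()], [element_sequence()]
#' @export
trap_element <- function(reporter_orf,
                         left_terminus,
                         right_terminus,
                         planned_sa_context,
                         ires_tag = NULL,
                         unplanned_sa_context = NULL,
                         ires_5p = NULL,
                         marker_spacer = "",
                         tail_spacer = "",
                         planned_sa_offset = 0L,
                         unplanned_sa_offset = 15L) {
  if (nchar(left_terminus) != 671L) {
    stop("left_terminus must be the 671-bp piggyBac 5' terminal sequence")
  }
  if (nchar(right_terminus) != 690L) {
    stop("right_terminus must be the 690-bp piggyBac 3' terminal sequence")
  }
  if (substr(reporter_orf, 1, 3) != "ATG") stop("reporter_orf must start with ATG")
  if (!endsWith(planned_sa_context, "AG")) {
    stop("planned_sa_context must end in the acceptor dinucleotide AG")
  }
  has_ires <- !is.null(ires_tag)
  if (has_ires) {
    if (nchar(ires_tag) != 15L) stop("ires_tag must be exactly 15 nt")
    if (is.null(unplanned_sa_context) || !endsWith(unplanned_sa_context, "AG")) {
      stop("IRES construct requires an unplanned_sa_context ending in AG")
    }
    if (is.null(ires_5p)) ires_5p <- ""
  }
  structure(list(
    construct = if (has_ires) "IRES" else "non_IRES",
    reporter_orf = reporter_orf,
    left_terminus = left_terminus,
    right_terminus = right_terminus,
    planned_sa_context = planned_sa_context,
    ires_tag = if (has_ires) ires_tag else NULL,
    unplanned_sa_context = if (has_ires) unplanned_sa_context else NULL,
    ires_5p = if (has_ires) ires_5p else NULL,
    marker_spacer = marker_spacer,
    tail_spacer = tail_spacer,
    planned_sa_offset = as.integer(planned_sa_offset),
    unplanned_sa_offset = as.integer(unplanned_sa_offset)
  ), class = "trap_element")
}

# Fixed internal seed: the default element is a package constant.
.element_seed <- 20180822L

#' Default promoter-trap elements
#'
#' Deterministic stand-ins for the two promoter-trap vectors used in a
#' screen: a non-IRES element (planned 3'-SA fused directly to the reporter
#' +1) and an IRES element (additional unplanned 3'-SA 15 nt upstream of
#' the reporter +1). The piggyBac termini, reporter ORF and internal
#' spacers are fixed pseudo-random sequences shared by both constructs;
#' the two published acceptor contexts are used verbatim:
#' planned `TTCCCCCCTCCCAGCAG`, unplanned `ATATCGTTAGTCTTTCAACAG`.
#'
#' @param construct which construct to build.
#' @return A `trap_element`.
#' @examples
#' el <- default_trap_element("IRES")
#' nchar(el$left_terminus)   # 671
#' @export
default_trap_element <- function(construct = c("IRES", "non_IRES")) {
  construct <- match.arg(construct)
  parts <- with_seed(.element_seed, {
    list(
      left = random_dna(671L),
      right = random_dna(690L),
      marker = random_dna(180L),
      tail = random_dna(120L),
      reporter = paste0("ATG", random_dna(687L)),
      ires_5p = random_dna(150L),
      ires_tag = random_dna(15L)
    )
  })
  if (construct == "non_IRES") {
    trap_element(
      reporter_orf = parts$reporter,
      left_terminus = parts$left,
      right_terminus = parts$right,
      planned_sa_context = "TTCCCCCCTCCCAGCAG",
      marker_spacer = parts$marker,
      tail_spacer = parts$tail
    )
  } else {
    trap_element(
      reporter_orf = parts$reporter,
      left_terminus = parts$left,
      right_terminus = parts$right,
      planned_sa_context = "TTCCCCCCTCCCAGCAG",
      ires_tag = parts$ires_tag,
      unplanned_sa_context = "ATATCGTTAGTCTTTCAACAG",
      ires_5p = parts$ires_5p,
      marker_spacer = parts$marker,
      tail_spacer = parts$tail
    )
  }
}

#' Both default elements, keyed by construct
#' @return named list with components `non_IRES` and `IRES`.
#' @export
default_elements <- function() {
  list(non_IRES = default_trap_element("non_IRES"),
       IRES = default_trap_element("IRES"))
}

#' Full nucleotide sequence of a trap element
#'
#' Concatenates the element parts in transcriptional (reporter-sense)
#' order: 5' terminus, marker cassette, planned splice acceptor,
#' (IRES + unplanned acceptor + retained tag,) reporter ORF, terminator
#' region, 3' terminus.
#'
#' @param element a `trap_element`.
#' @return a single DNA string.
#' @export
element_sequence <- function(element) {
  stopifnot(inherits(element, "trap_element"))
  if (element$construct == "IRES") {
    paste0(element$left_terminus, element$marker_spacer,
           element$planned_sa_context, element$ires_5p,
           element$unplanned_sa_context, element$ires_tag,
           element$reporter_orf, element$tail_spacer, element$right_terminus)
  } else {
    paste0(element$left_terminus, element$marker_spacer,
           element$planned_sa_context,
           element$reporter_orf, element$tail_spacer, element$right_terminus)
  }
}

# k-mer at the reporter +1 used as the junction marker.
marker_kmer <- function(element, k = 14L) substr(element$reporter_orf, 1L, k)

# Sequences that must not occur in the synthetic genome (either strand):
# the reporter +1 marker and the IRES retained tag.
default_exclude_kmers <- function(k = 14L) {
  els <- default_elements()
  unique(c(marker_kmer(els$non_IRES, k), els$IRES$ires_tag))
}

#' @export
print.trap_element <- function(x, ...) {
  cat(sprintf("trap_element (%s): reporter %d nt; termini %d/%d bp; element %d bp\n",
              x$construct, nchar(x$reporter_orf), nchar(x$left_terminus),
              nchar(x$right_terminus), nchar(element_sequence(x))))
  invisible(x)
}
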
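#' Extract splice-acceptor windows from annotated introns
#'
#' For every intron of every transcript, returns the intron-terminal
#' `width` nucleotides in transcript sense -- the window ending at the
#' acceptor AG. Introns shorter than `width` are skipped and counted.
#'
#' @param models `gene_models`.
#' @param genome named character vector, `DNAStringSet` or `trap_genome`.
#' @param width window width (default 21).
#' @return character vector of windows; attribute `n_skipped` counts
#'   introns shorter than `width`.
#' @export
extract_acceptor_windows <- function(models, genome, width = 21L) {
  if (width < 2L) stop("width must be at least 2 (the acceptor dinucleotide)")
  genome <- as_genome_vector(genome)
  out <- character(0)
  skipped <- 0L
  for (gid in models$genes$gene_id) {
    gi <- models$genes[models$genes$gene_id == gid, ]
    ints <- gene_introns(models, gid)
    for (k in seq_len(nrow(ints))) {
      len <- ints$end[k] - ints$start[k] + 1L
      if (len < width) {
        skipped <- skipped + 1L
        next
      }
      w <- if (gi$strand == "+") {
        substr(genome[[gi$scaffold]], ints$end[k] - width + 1L, ints$end[k])
      } else {
        revcomp(substr(genome[[gi$scaffold]], ints$start[k],
                       ints$start[k] + width - 1L))
      }
      out <- c(out, w)
    }
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Build a splice-acceptor conservation matrix
#'
#' Per-position base frequencies (with a pseudocount) over a set of
#' equal-width acceptor windows, the per-position information content
#' `IC_i = 2 + sum_b p_i(b) log2 p_i(b)` (bits: 0 for uniform base usage,
#' 2 for an invariant position), and the maximum attainable score under the
#' frequency-weighted scoring mode, `max_score = sum_i IC_i max_b p_i(b)`,
#' attained by the per-position consensus.
#'
#' @param windows character vector of equal-width DNA windows.
#' @param pseudocount added to every base count (default 1, Laplace;
#'   0 permitted).
#' @return object of class `acceptor_matrix`: `width`, `freqs` (4 x width
#'   matrix, rows A/C/G/T), `info_content`, `consensus`, `max_score`,
#'   `n_training`, `pseudocount`.
#' @examples
#' m <- build_acceptor_matrix(c("AAG", "CAG", "GAG", "TAG"), pseudocount = 0)
#' m$info_content  # 0, 2, 2
#' @export
build_acceptor_matrix <- function(windows, pseudocount = 1) {
  if (!length(windows)) stop("at least one window is required")
  wd <- unique(nchar(windows))
  if (length(wd) != 1L) stop("windows have mixed widths")
  if (any(grepl("[^ACGT]", windows))) stop("windows must be ACGT-only")
  bases <- c("A", "C", "G", "T")
  chars <- do.call(rbind, strsplit(windows, ""))
  counts <- vapply(seq_len(wd), function(j)
    vapply(bases, function(b) sum(chars[, j] == b), numeric(1)),
    numeric(4))
  counts <- matrix(counts, nrow = 4L, dimnames = list(bases, NULL))
  freqs <- sweep(counts + pseudocount, 2L,
                 colSums(counts) + 4 * pseudocount, "/")
  plogp <- freqs * log2(freqs)
  plogp[freqs == 0] <- 0
  ic <- 2 + colSums(plogp)
  cons_i <- apply(freqs, 2L, which.max)
  structure(list(
    width = wd,
    freqs = freqs,
    info_content = ic,
    consensus = paste(bases[cons_i], collapse = ""),
    max_score = sum(ic * apply(freqs, 2L, max)),
    n_training = length(windows),
    pseudocount = pseudocount
  ), class = "acceptor_matrix")
}

#' @export
print.acceptor_matrix <- function(x, ...) {
  cat(sprintf("acceptor_matrix: width %d, %d training windows, pseudocount %g\n",
              x$width, x$n_training, x$pseudocount))
  cat(sprintf("  consensus %s; max score %.4f; total IC %.2f bits\n",
              x$consensus, x$max_score, sum(x$info_content)))
  invisible(x)
}

#' Score a sequence against an acceptor matrix
#'
#' Default (`"frequency"`) mode scores
#' `sum_i IC_i * p_i(b_i)` over covered positions; `"consensus"` mode
#' scores `sum_i IC_i * [b_i == consensus_i]`. Sequences shorter than the
#' matrix width are right-aligned to the acceptor end (the last base of the
#' sequence scores at the last matrix position); uncovered positions
#' contribute 0. Scores never exceed `max_score` in frequency mode.
#'
#' @param matrix an `acceptor_matrix`.
#' @param seq DNA sequence of length at most `matrix$width`.
#' @param mode scoring mode.
#' @return numeric score.
#' @export
score_acceptor <- function(matrix, seq, mode = c("frequency", "consensus")) {
  mode <- match.arg(mode)
  L <- nchar(seq)
  if (L > matrix$width) {
    stop("sequence longer than matrix width; supply the acceptor-proximal ",
         matrix$width, " nt")
  }
  b <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(b), c("A", "C", "G", "T"))
  if (length(bad)) stop("non-ACGT character in sequence: ", paste(bad, collapse = ", "))
  pos <- (matrix$width - L + 1L):matrix$width
  if (mode == "frequency") {
    sum(matrix$info_content[pos] *
          matrix$freqs[cbind(match(b, c("A", "C", "G", "T")), pos)])
  } else {
    cons <- strsplit(matrix$consensus, "")[[1]][pos]
    sum(matrix$info_content[pos] * (b == cons))
  }
}

#' Write an acceptor matrix to TSV
#'
#' One row per position: base frequencies and information content.
#'
#' @param matrix an `acceptor_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_acceptor_matrix <- function(matrix, path) {
  df <- data.frame(position = seq_len(matrix$width),
                   t(matrix$freqs),
                   info_content = matrix$info_content)
  write_trap_tsv(df, path,
                 header_lines = sprintf("acceptor matrix: n_training=%d pseudocount=%g",
                                        matrix$n_training, matrix$pseudocount))
}

#' Read an acceptor matrix from TSV
#'
#' Accepts the [write_acceptor_matrix()] layout (columns `position`, `A`,
#' `C`, `G`, `T`, optional `info_content`): per-position base frequencies,
#' from which information content, consensus and max score are recomputed.
#'
#' @param path TSV path.
#' @return an `acceptor_matrix` (with `n_training = NA`).
#' @export
read_acceptor_matrix <- function(path) {
  df <- read_trap_tsv(path)
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(df))) stop("matrix file must have columns A, C, G, T")
  freqs <- t(as.matrix(df[, need]))
  sums <- colSums(freqs)
  if (any(abs(sums - 1) > 1e-6)) {
    freqs <- sweep(freqs, 2L, sums, "/")  # accept raw counts
  }
  plogp <- freqs * log2(freqs)
  plogp[freqs == 0] <- 0
  ic <- 2 + colSums(plogp)
  bases <- c("A", "C", "G", "T")
  structure(list(
    width = ncol(freqs),
    freqs = freqs,
    info_content = ic,
    consensus = paste(bases[apply(freqs, 2L, which.max)], collapse = ""),
    max_score = sum(ic * apply(freqs, 2L, max)),
    n_training = NA_integer_,
    pseudocount = NA_real_
  ), class = "acceptor_matrix")
}
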
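`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so library code never disturbs user simulations.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stage seeds derived from the master seed, kept inside integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% (.Machine$integer.max - 1))
}

# Uniform integer draw on [lo, hi]; avoids sample()'s scalar-x surprise.
rint <- function(n, lo, hi) {
  stopifnot(hi >= lo)
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
}

random_dna <- function(n) {
  paste(c("A", "C", "G", "T")[rint(n, 1L, 4L)], collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# Exact (or IUPAC, fixed = FALSE) matches of `pattern` in one sequence.
match_positions <- function(pattern, subject, fixed = TRUE) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject),
                                fixed = fixed)
  data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m))
}

#' Exact-match a tag against every scaffold, both strands
#'
#' @param tag DNA string to search for.
#' @param genome named character vector of scaffold sequences (or a
#'   `DNAStringSet` / `trap_genome` after [as_genome_vector()] coercion by
#'   the caller).
#' @param fixed `FALSE` enables IUPAC ambiguity codes in `tag`.
#' @return data.frame with `scaffold`, `start`, `end`, `strand` (1-based,
#'   fully closed).
#' @export
match_genome <- function(tag, genome, fixed = TRUE) {
  out <- list()
  rc <- revcomp(tag)
  for (sc in names(genome)) {
    p <- match_positions(tag, genome[[sc]], fixed = fixed)
    if (nrow(p)) out[[length(out) + 1L]] <- cbind(scaffold = sc, p, strand = "+")
    if (rc != tag) {
      m <- match_positions(rc, genome[[sc]], fixed = fixed)
    } else {
      m <- p[0, , drop = FALSE]
    }
    if (nrow(m)) out[[length(out) + 1L]] <- cbind(scaffold = sc, m, strand = "-")
  }
  if (!length(out)) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$start, res$strand), , drop = FALSE]
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

as_genome_vector <- function(genome) {
  if (inherits(genome, "trap_genome")) genome <- genome$genome
  if (methods::is(genome, "DNAStringSet")) {
    g <- as.character(genome)
    names(g) <- sub("\\s.*$", "", names(genome))
    return(g)
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ file path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ with uniform qualities
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(!is.null(names(reads)))
  lines <- as.vector(rbind(paste0("@", names(reads)),
                           unname(reads),
                           "+",
                           strrep("I", nchar(reads))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome to FASTA
#'
#' @param genome named character vector, `DNAStringSet`, or `trap_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  g <- as_genome_vector(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g), filepath = path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of scaffold sequences.
#' @export
read_genome_fasta <- function(path) {
  as_genome_vector(Biostrings::readDNAStringSet(path))
}

# TSV helpers: optional '#'-prefixed header lines carry provenance.
write_trap_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_trap_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
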
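#' Generate a synthetic genome with annotated gene models
#'
#' Builds `n_scaffolds` random scaffolds and places non-overlapping gene
#' models on random strands. Every gene carries at least one intron; a
#' fraction `frac_utr_intron` of genes (exact count, `round()`ed) carries a
#' 5'-UTR intron sized so that the distance from transcription start to the
#' ORF +1 falls in `utr_intron_5p_distance_range`. Every intron starts with
#' GT, ends with AG preceded by a pyrimidine-rich tract (so a splice-
#' acceptor conservation matrix is learnable from the annotation), and is
#' guaranteed to contain at least one TTAA piggyBac target site. Sequences
#' equal to `exclude_kmers` (by default the reporter +1 marker and the IRES
#' retained tag of the default trap elements) are scrubbed from both strands
#' so that exact-match junction detection has no background.
#'
#' Deterministic: the same `config` (including its seed) yields byte-
#' identical FASTA/GFF3 output.
#'
#' @param config a [synthetic_config()].
#' @param exclude_kmers character vector of k-mers that must not occur in
#'   the genome on either strand.
#' @return An object of class `trap_genome`: list with `genome` (named
#'   character vector of scaffolds), `models` (a `gene_models` object) and
#'   `config`.
#' @examples
#' gen <- generate_genome(synthetic_config(seed = 1, n_genes = 6,
#'                                         n_scaffolds = 2,
#'                                         scaffold_length = 60000,
#'                                         utr_intron_5p_distance_range = c(183, 8000)))
#' @export
generate_genome <- function(config, exclude_kmers = default_exclude_kmers()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    scaff_names <- sprintf("scaffold_%02d", seq_len(config$n_scaffolds))
    scaffolds <- vapply(scaff_names, function(s) random_dna(config$scaffold_length),
                        character(1))

    n_utr <- as.integer(round(config$frac_utr_intron * config$n_genes))
    utr_flag <- rep(FALSE, config$n_genes)
    if (n_utr > 0) utr_flag[sample.int(config$n_genes, n_utr)] <- TRUE

    gene_rows <- list()
    feat_rows <- list()
    margin <- 2000L
    sc_i <- 1L
    cursor <- margin
    for (i in seq_len(config$n_genes)) {
      g <- build_gene_local(utr_flag[i], config)
      gap <- rint(1L, 2000L, 6000L)
      while (cursor + gap + g$length + margin > config$scaffold_length) {
        sc_i <- sc_i + 1L
        cursor <- margin
        if (sc_i > config$n_scaffolds) {
          stop("scaffolds too short for requested gene count; increase ",
               "scaffold_length or n_scaffolds")
        }
      }
      gstart <- cursor + gap
      strand <- c("+", "-")[rint(1L, 1L, 2L)]
      placed <- place_gene(g, gstart, strand)
      sc <- scaff_names[sc_i]
      substr(scaffolds[[sc]], gstart, gstart + g$length - 1L) <- placed$seq

      gene_id <- sprintf("gene_%03d", i)
      gene_rows[[i]] <- data.frame(
        gene_id = gene_id, scaffold = sc, strand = strand,
        start = gstart, end = gstart + g$length - 1L,
        atg_pos = placed$atg_pos + gstart - 1L,
        cds_lo = placed$cds_lo + gstart - 1L,
        cds_hi = placed$cds_hi + gstart - 1L,
        has_utr_intron = utr_flag[i],
        stringsAsFactors = FALSE
      )
      f <- placed$features
      f$start <- f$start + gstart - 1L
      f$end <- f$end + gstart - 1L
      f$gene_id <- gene_id
      f$transcript_id <- paste0(gene_id, ".t1")
      f$scaffold <- sc
      f$strand <- strand
      feat_rows[[i]] <- f
      cursor <- gstart + g$length
    }

    scaffolds <- scrub_kmers(scaffolds, exclude_kmers)

    models <- new_gene_models(do.call(rbind, gene_rows), do.call(rbind, feat_rows))
    structure(list(genome = scaffolds, models = models, config = config),
              class = "trap_genome")
  })
}

# One gene in local (transcript-sense, 1-based) coordinates.
build_gene_local <- function(has_utr_intron, config) {
  ir <- config$intron_length_range
  n_ci <- rint(1L, 1L, 3L)
  cds_seg <- rint(n_ci + 1L, 120L, 400L)
  ci_len <- pmin(pmax(rint(n_ci, ir[1], ir[2]), 24L), ir[2])
  utr3 <- rint(1L, 80L, 250L)

  blocks <- list()  # list of c(kind, len, is_utr_intron)
  if (has_utr_intron) {
    dr <- config$utr_intron_5p_distance_range
    D <- rint(1L, dr[1], dr[2])
    e1 <- max(25L, min(150L, as.integer(floor((D - 80L) * 0.3))))
    u2 <- max(12L, min(80L, as.integer(floor((D - 80L) * 0.15))))
    # the 5'-UTR intron absorbs the transcription-start-to-ATG span; its
    # length is driven by the distance range, not intron_length_range
    Lu <- max(60L, D - e1 - u2)
    blocks <- c(blocks, list(c("E", e1, 0L), c("I", Lu, 1L),
                             c("E", u2 + cds_seg[1], 0L)))
    atg_local <- e1 + Lu + u2 + 1L
  } else {
    u1 <- rint(1L, 100L, 300L)
    blocks <- c(blocks, list(c("E", u1 + cds_seg[1], 0L)))
    atg_local <- u1 + 1L
  }
  for (j in seq_len(n_ci)) {
    blocks <- c(blocks, list(c("I", ci_len[j], 0L), c("E", cds_seg[j + 1L], 0L)))
  }
  blocks[[length(blocks)]][2] <- as.integer(blocks[[length(blocks)]][2]) + utr3

  pos <- 1L
  exons <- list(); introns <- list()
  for (b in blocks) {
    len <- as.integer(b[2])
    if (b[1] == "E") {
      exons[[length(exons) + 1L]] <- c(pos, pos + len - 1L)
    } else {
      introns[[length(introns) + 1L]] <- c(pos, pos + len - 1L, as.integer(b[3]))
    }
    pos <- pos + len
  }
  gene_len <- pos - 1L
  exons <- do.call(rbind, exons)
  introns <- do.call(rbind, introns)
  cds_end_local <- exons[nrow(exons), 2L] - utr3

  seq <- random_dna(gene_len)
  substr(seq, atg_local, atg_local + 2L) <- "ATG"
  substr(seq, cds_end_local - 2L, cds_end_local) <- "TAA"
  for (k in seq_len(nrow(introns))) {
    is <- introns[k, 1L]; ie <- introns[k, 2L]
    substr(seq, is, is + 1L) <- "GT"
    substr(seq, ie - 20L, ie) <- acceptor_21mer()
    mid <- as.integer((is + ie) / 2L)
    region <- substr(seq, is + 5L, ie - 25L)
    if (!grepl("TTAA", region, fixed = TRUE)) {
      substr(seq, mid, mid + 3L) <- "TTAA"
    }
  }

  list(seq = seq, length = gene_len,
       exons = exons, introns = introns,
       atg_local = atg_local, cds_end_local = cds_end_local)
}

# Intron-terminal 21-mer: pyrimidine-rich tract then NAG.
acceptor_21mer <- function() {
  paste0(random_dna(6L),
         paste(c("C", "T")[rint(12L, 1L, 2L)], collapse = ""),
         c("C", "T", "A")[rint(1L, 1L, 3L)], "AG")
}

# Strand-aware placement: returns sequence to write on the + strand plus
# feature coordinates in gene-local genomic (plus-strand) space.
place_gene <- function(g, gstart, strand) {
  L <- g$length
  flip <- function(m) {
    cbind(L - m[, 2L] + 1L, L - m[, 1L] + 1L,
          if (ncol(m) > 2L) m[, 3L] else NULL)
  }
  if (strand == "+") {
    seq <- g$seq
    exons <- g$exons
    atg_pos <- g$atg_local
    cds_lo <- g$atg_local; cds_hi <- g$cds_end_local
  } else {
    seq <- revcomp(g$seq)
    exons <- flip(g$exons)[, 1:2, drop = FALSE]
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    atg_pos <- L - g$atg_local + 1L
    cds_lo <- L - g$cds_end_local + 1L; cds_hi <- L - g$atg_local + 1L
  }
  feats <- feature_rows_from_exons(exons, cds_lo, cds_hi, strand)
  list(seq = seq, features = feats, atg_pos = atg_pos,
       cds_lo = cds_lo, cds_hi = cds_hi)
}

# exon/CDS/UTR rows (plus-strand coords) from exon intervals and CDS span.
# UTR labels follow transcript sense: on "-" the genomic left of the CDS is
# the 3'-UTR.
feature_rows_from_exons <- function(exons, cds_lo, cds_hi, strand) {
  utr_left <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
  utr_right <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
  rows <- list()
  add <- function(type, s, e) {
    if (s <= e) rows[[length(rows) + 1L]] <<- data.frame(
      type = type, start = as.integer(s), end = as.integer(e),
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(exons))) {
    s <- exons[k, 1L]; e <- exons[k, 2L]
    add("exon", s, e)
    add(utr_left, s, min(e, cds_lo - 1L))
    add("CDS", max(s, cds_lo), min(e, cds_hi))
    add(utr_right, max(s, cds_hi + 1L), e)
  }
  do.call(rbind, rows)
}

# Remove forbidden k-mers by mutating the middle base of each occurrence.
scrub_kmers <- function(scaffolds, kmers) {
  if (!length(kmers)) return(scaffolds)
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  repeat {
    dirty <- FALSE
    for (km in unique(c(kmers, revcomp(kmers)))) {
      for (sc in names(scaffolds)) {
        hits <- gregexpr(km, scaffolds[[sc]], fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        dirty <- TRUE
        for (h in hits) {
          p <- h + as.integer(nchar(km) / 2L)
          b <- substr(scaffolds[[sc]], p, p)
          substr(scaffolds[[sc]], p, p) <- rot[[b]]
        }
      }
    }
    if (!dirty) break
  }
  scaffolds
}

## ---- gene models container ----

new_gene_models <- function(genes, features) {
  rownames(genes) <- NULL
  rownames(features) <- NULL
  features <- features[, c("gene_id", "transcript_id", "scaffold", "strand",
                           "type", "start", "end")]
  o <- order(features$scaffold, features$start,
             match(features$type, c("exon", "five_prime_UTR", "CDS",
                                    "three_prime_UTR")))
  features <- features[o, ]
  rownames(features) <- NULL
  structure(list(genes = genes, features = features), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d scaffold(s); %d with 5'-UTR intron\n",
              nrow(x$genes), length(unique(x$genes$scaffold)),
              sum(x$genes$has_utr_intron)))
  invisible(x)
}

#' Introns of one transcript, in transcript order
#'
#' Introns are the gaps between consecutive exons, numbered 5' to 3' along
#' the transcript; 5'-UTR introns and coding introns share one ordinal
#' series. `is_utr` is `TRUE` when the intron lies entirely upstream of the
#' start codon in transcript sense.
#'
#' @param models a `gene_models` object.
#' @param gene_id gene identifier.
#' @return data.frame with `start`, `end` (1-based genomic), `ordinal`,
#'   `n_introns`, `is_utr`.
#' @export
gene_introns <- function(models, gene_id) {
  gi <- models$genes[models$genes$gene_id == gene_id, ]
  if (!nrow(gi)) stop("unknown gene_id: ", gene_id)
  ex <- models$features[models$features$gene_id == gene_id &
                          models$features$type == "exon", ]
  ex <- ex[order(ex$start), ]
  if (nrow(ex) < 2L) {
    return(data.frame(start = integer(0), end = integer(0),
                      ordinal = integer(0), n_introns = integer(0),
                      is_utr = logical(0)))
  }
  ints <- data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
  if (gi$strand == "+") {
    ints <- ints[order(ints$start), ]
    ints$is_utr <- ints$end < gi$atg_pos
  } else {
    ints <- ints[order(-ints$start), ]
    ints$is_utr <- ints$start > gi$atg_pos
  }
  ints$ordinal <- seq_len(nrow(ints))
  ints$n_introns <- nrow(ints)
  rownames(ints) <- NULL
  ints[, c("start", "end", "ordinal", "n_introns", "is_utr")]
}

#' Spliced transcript sequence of a gene
#'
#' @param models a `gene_models` object.
#' @param genome genome as named character vector (or `trap_genome`).
#' @param gene_id gene identifier.
#' @return one DNA string in transcript sense.
#' @export
transcript_sequence <- function(models, genome, gene_id) {
  genome <- as_genome_vector(genome)
  gi <- models$genes[models$genes$gene_id == gene_id, ]
  ex <- models$features[models$features$gene_id == gene_id &
                          models$features$type == "exon", ]
  ex <- ex[order(ex$start), ]
  parts <- substring(genome[[gi$scaffold]], ex$start, ex$end)
  s <- paste(parts, collapse = "")
  if (gi$strand == "-") s <- revcomp(s)
  s
}

## ---- GFF3 round trip ----

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon, CDS, five_prime_UTR and three_prime_UTR features
#' with ID/Parent attributes (1-based, fully-closed GFF3 convention).
#'
#' @param models a `gene_models` object (or a `trap_genome`).
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(models, path) {
  if (inherits(models, "trap_genome")) models <- models$models
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  f <- models$features

  mk <- function(scaffold, start, end, strand, type, id, parent, phase = NA_integer_) {
    gr <- GenomicRanges::GRanges(
      seqnames = scaffold,
      ranges = IRanges::IRanges(start = start, end = end),
      strand = strand)
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id
    S4Vectors::mcols(gr)$Parent <- parent
    S4Vectors::mcols(gr)$phase <- phase
    gr
  }
  # GFF3 phase for CDS segments, cumulative in transcript order.
  f$phase <- NA_integer_
  for (tx in unique(f$transcript_id)) {
    idx <- which(f$transcript_id == tx & f$type == "CDS")
    if (!length(idx)) next
    idx <- idx[order(f$start[idx])]
    if (f$strand[idx[1L]] == "-") idx <- rev(idx)
    lens <- f$end[idx] - f$start[idx] + 1L
    f$phase[idx] <- c(0L, (3L - cumsum(lens)[-length(lens)] %% 3L) %% 3L)
  }
  gene_gr <- mk(g$scaffold, g$start, g$end, g$strand, "gene", g$gene_id,
                NA_character_)
  mrna_gr <- mk(g$scaffold, g$start, g$end, g$strand, "mRNA",
                paste0(g$gene_id, ".t1"), g$gene_id)
  feat_gr <- mk(f$scaffold, f$start, f$end, f$strand, f$type,
                NA_character_, f$transcript_id, f$phase)
  all_gr <- c(gene_gr, mrna_gr, feat_gr)
  all_gr <- BiocGenerics::sort(all_gr, ignore.strand = TRUE)
  rtracklayer::export(all_gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models back from GFF3
#'
#' Reconstructs the in-memory `gene_models` representation from a GFF3 file
#' written by [write_annotation_gff3()] (or any GFF3 with gene/mRNA/exon/
#' CDS/UTR features and ID/Parent attributes; one transcript per gene).
#'
#' @param path GFF3 path.
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  parent <- vapply(df$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                   character(1))

  genes <- df[df$type == "gene", ]
  mrna <- df[df$type == "mRNA", ]
  tx_gene <- stats::setNames(parent[df$type == "mRNA"], mrna$ID)
  featsel <- df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  feats <- df[featsel, ]
  feats_tx <- parent[featsel]

  features <- data.frame(
    gene_id = unname(tx_gene[feats_tx]),
    transcript_id = feats_tx,
    scaffold = feats$seqnames,
    strand = feats$strand,
    type = feats$type,
    start = as.integer(feats$start),
    end = as.integer(feats$end),
    stringsAsFactors = FALSE
  )

  gene_rows <- data.frame(
    gene_id = genes$ID, scaffold = genes$seqnames, strand = genes$strand,
    start = as.integer(genes$start), end = as.integer(genes$end),
    stringsAsFactors = FALSE
  )
  # Derive CDS span / ATG from CDS features.
  gene_rows$atg_pos <- NA_integer_
  gene_rows$cds_lo <- NA_integer_
  gene_rows$cds_hi <- NA_integer_
  gene_rows$has_utr_intron <- FALSE
  for (i in seq_len(nrow(gene_rows))) {
    gid <- gene_rows$gene_id[i]
    cds <- features[features$gene_id == gid & features$type == "CDS", ]
    if (nrow(cds)) {
      lo <- min(cds$start); hi <- max(cds$end)
      gene_rows$cds_lo[i] <- lo
      gene_rows$cds_hi[i] <- hi
      gene_rows$atg_pos[i] <- if (gene_rows$strand[i] == "+") lo else hi
    }
  }
  models <- new_gene_models(gene_rows, features)
  for (i in seq_len(nrow(models$genes))) {
    ints <- gene_introns(models, models$genes$gene_id[i])
    models$genes$has_utr_intron[i] <- any(ints$is_utr)
  }
  models
}
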
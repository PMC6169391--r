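#' Plant promoter-trap insertions at TTAA sites
#'
#' Selects TTAA tetranucleotides inside annotated features of a synthetic
#' genome and integrates the full trap element with the piggyBac target-site
#' duplication: the single genomic `TTAA` is replaced by
#' `TTAA + element + TTAA`. Per construct, `n_insertions_per_construct`
#' sites are drawn across feature classes (5'-UTR introns, coding introns,
#' exons, 3'-UTRs, intergenic) and both element orientations relative to the
#' host transcript are represented; at least one same-strand intronic
#' insertion per construct is guaranteed so that each construct can produce
#' fusion transcripts.
#'
#' @param gen a `trap_genome` from [generate_genome()].
#' @param elements named list with `non_IRES` and `IRES` [trap_element()]s.
#' @param config the [synthetic_config()] (defaults to `gen$config`).
#' @param class_weights named allocation weights over feature classes.
#' @return list with `modified` (named character vector of scaffolds with
#'   all elements integrated) and `truth` (data.frame, one row per planted
#'   insertion; coordinates refer to the unmodified genome).
#' @export
plant_insertions <- function(gen, elements = default_elements(),
                             config = gen$config,
                             class_weights = c(five_prime_utr_intron = 0.45,
                                               coding_intron = 0.30,
                                               exon = 0.10,
                                               three_prime_utr = 0.05,
                                               intergenic = 0.10)) {
  stopifnot(inherits(gen, "trap_genome"))
  models <- gen$models
  genome <- gen$genome
  n_per <- config$n_insertions_per_construct
  margin <- 2000L

  with_seed(derive_seed(config$seed, 1), {
    pools <- ttaa_pools(genome, models, margin)
    counts <- allocate_counts(class_weights, n_per)

    truth <- list()
    used <- character(0)
    iid <- 0L
    for (construct in c("non_IRES", "IRES")) {
      first_intronic <- TRUE
      for (cls in names(counts)) {
        need <- counts[[cls]]
        if (need == 0L) next
        pool <- pools[[cls]]
        pool_keys <- paste(pool$scaffold, pool$start)
        pool <- pool[!(pool_keys %in% used), , drop = FALSE]
        if (nrow(pool) < need) {
          stop(sprintf("no free TTAA site available in feature class '%s'", cls))
        }
        pick <- pool[sample.int(nrow(pool), need), , drop = FALSE]
        for (r in seq_len(need)) {
          iid <- iid + 1L
          row <- pick[r, ]
          used <- c(used, paste(row$scaffold, row$start))
          genic <- cls != "intergenic"
          same <- if (genic && first_intronic &&
                      cls %in% c("five_prime_utr_intron", "coding_intron")) {
            first_intronic <- FALSE
            TRUE
          } else {
            stats::runif(1) < 0.6
          }
          if (genic) {
            gstrand <- models$genes$strand[models$genes$gene_id == row$gene_id]
            estrand <- if (same) gstrand else setdiff(c("+", "-"), gstrand)
            orientation <- if (same) "same_strand" else "opposite_strand"
          } else {
            estrand <- c("+", "-")[rint(1L, 1L, 2L)]
            orientation <- NA_character_
          }
          dist <- if (genic) {
            gi <- models$genes[models$genes$gene_id == row$gene_id, ]
            if (gi$strand == "+") gi$atg_pos - row$start else row$start - gi$atg_pos
          } else NA_integer_
          truth[[iid]] <- data.frame(
            insertion_id = sprintf("ins_%03d", iid),
            scaffold = row$scaffold,
            ttaa_start = row$start,
            element_strand = estrand,
            orientation = orientation,
            construct = construct,
            true_feature_class = cls,
            true_gene_id = if (genic) row$gene_id else NA_character_,
            true_intron_ordinal = row$ordinal,
            true_n_introns = row$n_introns,
            true_distance_to_orf_start = dist,
            chimeric_read_ids = "",
            stringsAsFactors = FALSE
          )
        }
      }
    }
    truth <- do.call(rbind, truth)

    # Guarantee both orientations among genic insertions.
    genic_idx <- which(!is.na(truth$orientation))
    if (length(genic_idx) >= 2L && length(unique(truth$orientation[genic_idx])) == 1L) {
      i <- genic_idx[length(genic_idx)]
      gstrand <- models$genes$strand[models$genes$gene_id == truth$true_gene_id[i]]
      truth$orientation[i] <- setdiff(c("same_strand", "opposite_strand"),
                                      truth$orientation[i])
      truth$element_strand[i] <- if (truth$orientation[i] == "same_strand") {
        gstrand
      } else setdiff(c("+", "-"), gstrand)
    }

    modified <- integrate_elements(genome, truth, elements)
    list(modified = modified, truth = truth)
  })
}

# Candidate TTAA sites per feature class. Sites keep a margin from scaffold
# ends so splinkerette fragments stay within the assembly.
ttaa_pools <- function(genome, models, margin) {
  pools <- list(five_prime_utr_intron = list(), coding_intron = list(),
                exon = list(), three_prime_utr = list(), intergenic = list())
  for (gid in models$genes$gene_id) {
    gi <- models$genes[models$genes$gene_id == gid, ]
    ints <- gene_introns(models, gid)
    seqsc <- genome[[gi$scaffold]]
    for (k in seq_len(nrow(ints))) {
      hits <- match_positions("TTAA", substr(seqsc, ints$start[k] + 5L,
                                             ints$end[k] - 25L))
      if (!nrow(hits)) next
      cls <- if (ints$is_utr[k]) "five_prime_utr_intron" else "coding_intron"
      pools[[cls]][[length(pools[[cls]]) + 1L]] <- data.frame(
        scaffold = gi$scaffold, start = hits$start + ints$start[k] + 4L,
        gene_id = gid, ordinal = ints$ordinal[k], n_introns = ints$n_introns[k],
        stringsAsFactors = FALSE)
    }
    fx <- models$features[models$features$gene_id == gid, ]
    for (type in c("exon", "three_prime_UTR")) {
      cls <- if (type == "exon") "exon" else "three_prime_utr"
      sub <- fx[fx$type == type, ]
      for (k in seq_len(nrow(sub))) {
        s <- sub$start[k] + 5L; e <- sub$end[k] - 5L
        if (e - s < 10L) next
        hits <- match_positions("TTAA", substr(seqsc, s, e))
        if (!nrow(hits)) next
        pos <- hits$start + s - 1L
        if (type == "exon" && nrow(fx[fx$type == "three_prime_UTR", ])) {
          u <- fx[fx$type == "three_prime_UTR", ]
          in_utr3 <- vapply(pos, function(p) any(p >= u$start & p <= u$end),
                            logical(1))
          pos <- pos[!in_utr3]
        }
        if (!length(pos)) next
        pools[[cls]][[length(pools[[cls]]) + 1L]] <- data.frame(
          scaffold = gi$scaffold, start = pos, gene_id = gid,
          ordinal = NA_integer_, n_introns = nrow(ints),
          stringsAsFactors = FALSE)
      }
    }
  }
  # Intergenic: TTAA at least 1 kb from any gene, margin from scaffold ends.
  for (sc in names(genome)) {
    g <- models$genes[models$genes$scaffold == sc, ]
    hits <- match_positions("TTAA", genome[[sc]])
    if (!nrow(hits)) next
    pos <- hits$start
    pos <- pos[pos > margin & pos < nchar(genome[[sc]]) - margin]
    if (nrow(g)) {
      near <- vapply(pos, function(p) any(p >= g$start - 1000L &
                                            p <= g$end + 1000L), logical(1))
      pos <- pos[!near]
    }
    if (!length(pos)) next
    pools$intergenic[[length(pools$intergenic) + 1L]] <- data.frame(
      scaffold = sc, start = pos, gene_id = NA_character_,
      ordinal = NA_integer_, n_introns = NA_integer_, stringsAsFactors = FALSE)
  }
  lapply(pools, function(p) {
    if (!length(p)) {
      data.frame(scaffold = character(0), start = integer(0),
                 gene_id = character(0), ordinal = integer(0),
                 n_introns = integer(0))
    } else {
      do.call(rbind, p)
    }
  })
}

# Largest-remainder allocation of n over weights.
allocate_counts <- function(weights, n) {
  w <- weights / sum(weights)
  raw <- w * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  stats::setNames(as.integer(cnt), names(weights))
}

# Apply all insertions to scaffold sequences (rightmost first so earlier
# coordinates stay valid). TTAA target-site duplication.
integrate_elements <- function(genome, truth, elements) {
  for (sc in unique(truth$scaffold)) {
    rows <- truth[truth$scaffold == sc, ]
    rows <- rows[order(-rows$ttaa_start), ]
    s <- genome[[sc]]
    for (r in seq_len(nrow(rows))) {
      el <- elements[[rows$construct[r]]]
      eseq <- element_sequence(el)
      if (rows$element_strand[r] == "-") eseq <- revcomp(eseq)
      p <- rows$ttaa_start[r]
      s <- paste0(substr(s, 1L, p + 3L), eseq, "TTAA",
                  substr(s, p + 4L, nchar(s)))
    }
    genome[[sc]] <- s
  }
  genome
}
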
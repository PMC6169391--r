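# Shared fixtures, built in code and cached for the session.

.world_cache <- new.env(parent = emptyenv())

tiny_config <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_scaffolds = 2L, scaffold_length = 80000L,
               n_genes = 8L,
               utr_intron_5p_distance_range = c(183L, 8000L),
               n_insertions_per_construct = 5L, n_read_pairs = 400L,
               chimera_fraction = 0.1)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# A complete small synthetic screen: genome, planted insertions, flanks,
# reads, truth. Cached per (tag, seed).
make_world <- function(config, tag) {
  key <- paste0(tag, "_", config$seed)
  if (is.null(.world_cache[[key]])) {
    els <- default_elements()
    gen <- generate_genome(config)
    pl <- plant_insertions(gen, els)
    fl <- simulate_splinkerette(gen$genome, pl$truth, els, config$enzyme)
    rd <- simulate_reads(gen, pl$truth, els)
    .world_cache[[key]] <- list(cfg = config, els = els, gen = gen,
                                modified = pl$modified, truth = rd$truth,
                                flanks = fl, r1 = rd$r1, r2 = rd$r2)
  }
  .world_cache[[key]]
}

tiny_world <- function(seed = 11L) make_world(tiny_config(seed), "tiny")

# Study-scale world used by the acceptance checks (>= 40 planted
# insertions, both constructs, both orientations, default geometry).
study_world <- function(seed = 101L) {
  make_world(synthetic_config(seed = seed), "study")
}

chimeric_ids <- function(truth) {
  unlist(strsplit(truth$chimeric_read_ids[nchar(truth$chimeric_read_ids) > 0],
                  ",", fixed = TRUE))
}

# Engineered read pair: junction mate = genomic tag + reporter +1 prefix;
# mate = reverse complement of an internal reporter substring (standard
# forward-reverse geometry).
engineered_pair <- function(tag_len, reporter_len, mate_len,
                            element = default_trap_element("non_IRES"),
                            mate_from = 100L, flip_mate = TRUE,
                            insert = "") {
  rep_orf <- element$reporter_orf
  tag <- substr(paste0(strrep("ACGGT", 20L)), 1L, tag_len)
  junction <- paste0(tag, insert, substr(rep_orf, 1L, reporter_len))
  sub <- substr(rep_orf, mate_from, mate_from + mate_len - 1L)
  mate <- if (flip_mate) revcomp(sub) else sub
  list(r1 = c(p1 = junction), r2 = c(p1 = mate))
}

# Minimal hand-written GFF3 + genome for boundary tests.
toy_gene_world <- function() {
  gff <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1\t60\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t1\t60\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttoy\texon\t1\t10\t.\t+\t.\tParent=g1.t1",
    "chr1\ttoy\texon\t31\t60\t.\t+\t.\tParent=g1.t1",
    "chr1\ttoy\tfive_prime_UTR\t1\t10\t.\t+\t.\tParent=g1.t1",
    "chr1\ttoy\tfive_prime_UTR\t31\t34\t.\t+\t.\tParent=g1.t1",
    "chr1\ttoy\tCDS\t35\t55\t.\t+\t0\tParent=g1.t1",
    "chr1\ttoy\tthree_prime_UTR\t56\t60\t.\t+\t.\tParent=g1.t1")
  path <- tempfile(fileext = ".gff3")
  writeLines(gff, path)
  models <- read_gene_models(path)
  # intron 11..30 ends in TTTTCAG; donor GT at 11
  intron <- paste0("GT", "AAGCCTTAAGC", "TTTTCAG")
  stopifnot(nchar(intron) == 20L)
  exon1 <- "ACGTACGTAC"
  exon2 <- paste0("GCCA", "ATGCCCGGGTTTACGTAATAA", "CCCCC")
  stopifnot(nchar(exon2) == 30L)
  genome <- c(chr1 = paste0(exon1, intron, exon2))
  list(models = models, genome = genome)
}
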
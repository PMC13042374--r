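# Shared in-code fixtures. Everything is deterministic; heavier simulated
# cohorts are built lazily and memoised for the session.

# a tiny explicit reference with known motif placements
tiny_reference <- function() {
  # chrT: positions chosen so that 4-mers at fixed offsets are known
  seq <- paste0(
    "ACGTACGTCCCATTGGGACCTCCGAGGAGT",  # 0..29
    strrep("ACGT", 30),                 # 30..149
    "CCCAAAAATGGGCCTCCTTGGAGTTTTTTT",  # 150..179
    strrep("TGCA", 30)                  # 180..299
  )
  reference_genome(
    Biostrings::DNAStringSet(c(chrT = seq)),
    genes = tibble::tibble(
      gene = "gT", chrom = "chrT", start = 100L, end = 250L,
      strand = "+", tss = 100L
    )
  )
}

# memoised default simulated world shared across test files
sim_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_controls = 4, n_cancers = 4)
      ref <- simulate_reference(cfg, seed = 42)
      pool <- load_synthetic_pool()
      coh <- simulate_cohort(cfg, ref, pool, seed = 42)
      idx <- attr(coh, "sim_index")
      panel <- simulate_panel(cfg, ref, seed = 42, index = idx)
      cache <<- list(cfg = cfg, ref = ref, pool = pool, cohort = coh,
                     index = idx, panel = panel,
                     end_model = build_end_model(panel),
                     classifier = region_classifier(ref$reference$genes))
    }
    cache
  }
})

random_fragments <- function(n, chrom = "chrT", min_start = 10,
                             max_start = 200, lengths = 50:80, seed = 1) {
  set.seed(seed)
  start <- sample(min_start:max_start, n, replace = TRUE)
  tibble::tibble(
    chrom = chrom,
    start = start,
    end = start + sample(lengths, n, replace = TRUE),
    fragment_id = sprintf("r%03d", seq_len(n)),
    mapq = 60L,
    strand = "+"
  )
}
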
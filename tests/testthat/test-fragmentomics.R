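test_that("allele partition assigns Mut/Wt and excludes multi-locus reads", {
  frags <- tibble::tibble(
    chrom = "chr1",
    start = c(90L, 95L, 200L, 50L, 205L),
    end = c(190L, 195L, 260L, 250L, 300L),
    fragment_id = c("a", "b", "c", "d", "e")
  )
  loci <- tibble::tibble(chrom = "chr1", pos = c(150L, 220L), ref = "A",
                         alt = "G")
  base_calls <- tibble::tibble(
    fragment_id = c("a", "b", "c"),
    chrom = "chr1", pos = c(150L, 150L, 220L),
    base = c("G", "A", "T")
  )
  part <- partition_by_allele(frags, base_calls, loci)
  expect_equal(part$mut$fragment_id, "a")       # carries alt
  expect_equal(part$wt$fragment_id, "b")        # carries ref
  expect_equal(part$excluded_multi, 1L)          # d spans both loci
  expect_equal(part$dropped_other_allele, 1L)    # c carries a third allele
  expect_equal(part$dropped_no_call, 1L)         # e has no call at its locus
})

test_that("scripted partition equals an exhaustive per-fragment check", {
  set.seed(21)
  n <- 100
  frags <- tibble::tibble(
    chrom = "chr1",
    start = sample(0:900, n, replace = TRUE)
  ) %>% dplyr::mutate(end = start + sample(80:160, n, replace = TRUE),
                      fragment_id = sprintf("f%03d", 1:n))
  loci <- tibble::tibble(chrom = "chr1", pos = c(101L, 301L, 501L, 701L,
                                                 901L),
                         ref = "A", alt = "C")
  # every fragment gets a call at every locus it overlaps
  base_calls <- purrr::map_dfr(seq_len(n), function(i) {
    ov <- loci$pos - 1 >= frags$start[i] & loci$pos - 1 < frags$end[i]
    if (!any(ov)) return(NULL)
    tibble::tibble(fragment_id = frags$fragment_id[i], chrom = "chr1",
                   pos = loci$pos[ov],
                   base = sample(c("A", "C", "G"), sum(ov), replace = TRUE,
                                 prob = c(0.6, 0.3, 0.1)))
  })
  part <- partition_by_allele(frags, base_calls, loci)
  # oracle: enumerate
  n_ov <- vapply(seq_len(n), function(i) {
    sum(loci$pos - 1 >= frags$start[i] & loci$pos - 1 < frags$end[i])
  }, numeric(1))
  expect_equal(part$excluded_multi, sum(n_ov >= 2))
  single <- which(n_ov == 1)
  oracle_class <- vapply(single, function(i) {
    lp <- loci$pos[loci$pos - 1 >= frags$start[i] & loci$pos - 1 < frags$end[i]]
    b <- base_calls$base[base_calls$fragment_id == frags$fragment_id[i] &
                           base_calls$pos == lp]
    if (length(b) == 0) "drop" else if (b == "C") "mut"
    else if (b == "A") "wt" else "other"
  }, character(1))
  expect_equal(sort(part$mut$fragment_id),
               sort(frags$fragment_id[single][oracle_class == "mut"]))
  expect_equal(sort(part$wt$fragment_id),
               sort(frags$fragment_id[single][oracle_class == "wt"]))
})

test_that("short-fragment fraction uses the inclusive 150 bp boundary", {
  mk <- function(lens) tibble::tibble(chrom = "c", start = 0L,
                                      end = as.integer(lens))
  expect_equal(frac_short(mk(c(150, 151))), 0.5)
  expect_equal(frac_short(mk(rep(166, 5))), 0)
  expect_true(is.na(frac_short(mk(integer(0)))))
  set.seed(8)
  lens <- c(round(rnorm(600, 166, 10)), round(rnorm(400, 140, 8)))
  expect_equal(frac_short(mk(lens)), mean(lens <= 150))
})

test_that("end motifs read both termini strand-aware from the reference", {
  ref <- tiny_reference()
  # chrT[8..11] (0-based) = "CCCA"; D end with forward TGGG at 13..16
  # yields reverse-complement motif CCCA
  frag <- tibble::tibble(chrom = "chrT", start = 8L, end = 17L,
                         fragment_id = "x")
  em <- end_motifs(frag, ref)
  expect_equal(motif_fraction(em, "CCCA"), 1.0)
  expect_equal(attr(em, "n_ends"), 2L)

  # u_end at "CCGA": build explicit reference
  ref2 <- reference_genome(c(c1 = "TTCCGATTTTTTCGGTT"))
  frag2 <- tibble::tibble(chrom = "c1", start = 2L, end = 15L,
                          fragment_id = "y")
  em2 <- end_motifs(frag2, ref2)
  # U end [2..5] = "CCGA"; D end d_end = 14, forward [11..14] = "TCGG"
  # -> reverse complement "CCGA": both termini give the same motif
  expect_equal(motif_fraction(em2, "CCGA"), 1.0)
  expect_equal(sum(em2$freq), 1)

  # terminus too close to the contig edge is skipped with a count
  frag3 <- tibble::tibble(chrom = "c1", start = 14L, end = 17L,
                          fragment_id = "z")
  em3 <- end_motifs(frag3, ref2)
  expect_equal(attr(em3, "n_skipped"), 1L)  # U end needs 4 bases inward
})

test_that("motif tallies match a direct count on simulated fragments", {
  w <- sim_world()
  frags <- w$panel[1:500, ]
  em <- end_motifs(frags, w$ref$reference)
  # oracle: substring tally
  s <- as.character(w$ref$reference$seq[[1]])
  rc <- function(x) chartr("ACGT", "TGCA", sapply(strsplit(x, ""), function(v)
    paste(rev(v), collapse = "")))
  u <- substring(s, frags$start + 1, frags$start + 4)
  d <- rc(substring(s, frags$end - 3, frags$end))
  tab <- table(c(u, d))
  for (m in names(tab)) {
    expect_equal(em$count[em$motif == m], as.integer(tab[[m]]), label = m)
  }
})

test_that("breakpoint motifs span the cut with two bases on each side", {
  # reference ...C T | C C A...: cut at | as U end gives CTCC
  ref <- reference_genome(c(c1 = "AAACTCCAGGGGGGGGTT"))
  frag <- tibble::tibble(chrom = "c1", start = 5L, end = 14L,
                         fragment_id = "x")
  bm <- breakpoint_motifs(frag, ref)
  expect_equal(motif_fraction(bm, "CTCC"), 0.5)
  # D end: d_end = 13 (0-based), forward [12..15] = "GGGG" -> rc "CCCC"
  expect_equal(motif_fraction(bm, "CCCC"), 0.5)

  # cuts placed after AA before TT never produce CTCC
  ref2 <- reference_genome(c(c2 = paste0(strrep("A", 10), strrep("T", 10))))
  frag2 <- tibble::tibble(chrom = "c2", start = 10L, end = 16L,
                          fragment_id = "y")
  bm2 <- breakpoint_motifs(frag2, ref2)
  expect_equal(motif_fraction(bm2, "CTCC"), 0)

  # tally oracle on simulated fragments
  w <- sim_world()
  frags <- w$panel[1:300, ]
  bm3 <- breakpoint_motifs(frags, w$ref$reference)
  s <- as.character(w$ref$reference$seq[[1]])
  rc <- function(x) chartr("ACGT", "TGCA", sapply(strsplit(x, ""), function(v)
    paste(rev(v), collapse = "")))
  u <- substring(s, frags$start - 1, frags$start + 2)
  d <- rc(substring(s, frags$end - 1, frags$end + 2))
  tab <- table(c(u, d))
  for (m in names(tab)) {
    expect_equal(bm3$count[bm3$motif == m], as.integer(tab[[m]]), label = m)
  }
})

test_that("motif diversity hits its closed-form extremes", {
  expect_equal(motif_diversity(rep(1 / 256, 256)), 1.0)
  one_hot <- c(1, rep(0, 255))
  expect_equal(motif_diversity(one_hot), 0.0)
  two <- c(0.5, 0.5, rep(0, 254))
  expect_equal(motif_diversity(two), log(2) / log(256))
  expect_equal(motif_diversity(two), 0.125)
  expect_error(motif_diversity(c(-0.1, rep(1.1 / 255, 255))), "nonnegative")
})

test_that("end model tallies U and D ends orientation-aware", {
  frags <- tibble::tibble(
    chrom = "chr1", start = c(100L, 100L, 200L),
    end = c(180L, 190L, 280L), fragment_id = c("a", "b", "c")
  )
  m <- build_end_model(frags)
  expect_equal(m$total_ends, 6L)
  cnt <- m$counts
  expect_equal(cnt$u_count[cnt$pos == 100], 2L)
  expect_equal(cnt$d_count[cnt$pos == 179], 1L)
  expect_equal(sum(cnt$u_count) + sum(cnt$d_count), 6L)
  expect_error(build_end_model(frags[0, ]), "empty")

  one <- build_end_model(frags[1, ])
  expect_equal(one$total_ends, 2L)

  # round-trip through TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_end_model(m, path)
  back <- read_end_model(path)
  expect_equal(back$counts, m$counts, ignore_attr = TRUE)
  expect_equal(back$scale, m$scale)
})

test_that("E-index equals the per-fragment summation brute force", {
  # identity case: all U ends share count a, D ends count b
  panel <- tibble::tibble(
    chrom = "chr1",
    start = rep(100L, 4), end = rep(200L, 4),
    fragment_id = paste0("p", 1:4)
  )
  m <- build_end_model(panel)  # u_counts[100] = 4, d_counts[199] = 4
  sample_frags <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
                                 fragment_id = "s1")
  expect_equal(e_index(sample_frags, m), m$scale * (4 + 4))
  expect_equal(e_index(sample_frags, m, normalized = FALSE), 8)

  # ends absent from the model contribute zero
  off <- tibble::tibble(chrom = "chr1", start = 500L, end = 600L,
                        fragment_id = "s2")
  expect_equal(e_index(off, m), 0)

  # 200 scripted fragments vs brute-force double loop
  w <- sim_world()
  frags <- w$cohort$samples$control_01$fragments[1:200, ]
  model <- w$end_model
  got <- e_index(frags, model)
  brute <- mean(vapply(seq_len(nrow(frags)), function(i) {
    u <- model$counts$u_count[model$counts$chrom == frags$chrom[i] &
                                model$counts$pos == frags$start[i]]
    d <- model$counts$d_count[model$counts$chrom == frags$chrom[i] &
                                model$counts$pos == frags$end[i] - 1]
    model$scale * (sum(u) + sum(d))
  }, numeric(1)))
  expect_equal(got, brute, tolerance = 1e-12)

  # order invariance and linear scaling in the model scale
  expect_equal(e_index(frags[sample(nrow(frags)), ], model), got)
  model2 <- model; model2$scale <- model$scale * 3
  expect_equal(e_index(frags, model2), 3 * got, tolerance = 1e-12)
})

test_that("nucleosome end fraction uses inclusive +/-50 bp and signed distances", {
  centers <- tibble::tibble(chrom = "chr1", center = c(1000L, 2000L))
  at_center <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2001L,
                              fragment_id = "a")
  res <- nucleosome_end_fraction(at_center, centers)
  expect_equal(res$fraction, 100)

  # boundary: +50 inside, +51 outside
  b <- tibble::tibble(chrom = "chr1", start = 1050L, end = 2052L,
                      fragment_id = "b")
  res_b <- nucleosome_end_fraction(b, centers)
  expect_equal(res_b$fraction, 50)
  expect_equal(sort(res_b$distances$distance), c(50, 51))

  # sign: end upstream of its nearest center is negative
  c2 <- tibble::tibble(chrom = "chr1", start = 990L, end = 1990L,
                       fragment_id = "c")
  dist_c <- nucleosome_end_fraction(c2, centers)$distances
  expect_equal(dist_c$distance[dist_c$pos == 990], -10)

  # chromosome without centers excluded with a count
  mixed <- tibble::tibble(chrom = c("chr1", "chr9"), start = c(1000L, 5L),
                          end = c(1100L, 105L),
                          fragment_id = c("d", "e"))
  res_m <- nucleosome_end_fraction(mixed, centers)
  expect_equal(res_m$excluded, 2L)

  # exhaustive nearest-neighbour scan oracle on scripted data
  set.seed(13)
  cc <- tibble::tibble(chrom = "chr1",
                       center = sort(sample(0:5000, 40)))
  ff <- tibble::tibble(chrom = "chr1", start = sample(100:4800, 150,
                                                      replace = TRUE)) %>%
    dplyr::mutate(end = start + 120L,
                  fragment_id = sprintf("f%d", dplyr::row_number()))
  got <- nucleosome_end_fraction(ff, cc)
  ends <- c(ff$start, ff$end - 1L)
  brute <- vapply(ends, function(p) {
    d <- p - cc$center
    d[which.min(abs(d))[1]]
  }, numeric(1))
  expect_equal(got$fraction, 100 * mean(abs(brute) <= 50))

  # invariance under a global coordinate shift
  shift <- 1234L
  got_s <- nucleosome_end_fraction(
    dplyr::mutate(ff, start = start + shift, end = end + shift),
    dplyr::mutate(cc, center = center + shift))
  expect_equal(got_s$fraction, got$fraction)
})

test_that("diff features subtract Wt from Mut and propagate undefined", {
  expect_equal(diff_metric(0.30, 0.18), 0.12)
  expect_equal(diff_metric(1, 1), 0)
  expect_true(is.na(diff_metric(NA_real_, 0.5)))

  w <- sim_world()
  s <- w$cohort$samples$cancer_01
  scr <- screen_sample(s, w$ref$reference)
  part <- partition_by_allele(s$fragments, s$base_calls, scr$retained)
  d <- diff_features(part, w$ref$reference, w$end_model, w$ref$nucleosomes)
  expect_equal(d$diff_size, d$mut_frac_short - d$wt_frac_short)
})
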
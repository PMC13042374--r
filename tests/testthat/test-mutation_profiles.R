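test_that("profiles bin substitutions with pyrimidine-strand collapsing", {
  # reference around pos 2 is A-C-G (chrM1: "ACGT...")
  ref <- reference_genome(c(chr1 = "ACGTTTCACGT"))
  one <- build_profile(
    tibble::tibble(chrom = "chr1", pos = 2L, ref = "C", alt = "T"), ref)
  expect_equal(sum(one$count), 1)
  expect_equal(one$frequency[one$context == "A[C>T]G"], 1.0)

  # purine reference collapses by reverse complement: G>A with flanks C_T
  # (context CGT) maps to A[C>T]G as well
  two <- build_profile(
    tibble::tibble(chrom = "chr1", pos = 10L, ref = "G", alt = "A"), ref)
  expect_equal(two$frequency[two$context == "A[C>T]G"], 1.0)

  # permutation invariance and frequency normalization
  set.seed(5)
  w <- sim_world()
  calls <- w$cohort$samples$cancer_01$truth$variants
  p1 <- build_profile(calls, w$ref$reference)
  p2 <- build_profile(calls[sample(nrow(calls)), ], w$ref$reference)
  expect_equal(p1, p2, ignore_attr = TRUE)
  expect_equal(sum(p1$frequency), 1)
})

test_that("scripted calls match a per-call hand count", {
  ref <- reference_genome(c(chr1 = "AACATTCCGGAATTCCGG"))
  calls <- tibble::tibble(
    chrom = "chr1",
    pos = c(3L, 3L, 3L, 8L, 8L, 9L, 13L, 14L, 15L, 16L),
    ref = c("C", "C", "C", "C", "C", "C", "T", "T", "C", "C"),
    alt = c("T", "T", "G", "A", "A", "G", "A", "C", "A", "G")
  )
  prof <- build_profile(calls, ref)
  # independent enumeration: count context labels by hand-derived rules
  s <- "AACATTCCGGAATTCCGG"
  expect_hand <- table(vapply(seq_len(nrow(calls)), function(i) {
    p <- calls$pos[i]
    tri <- substr(s, p - 1, p + 1)
    r <- calls$ref[i]; a <- calls$alt[i]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (r %in% c("A", "G")) {
      lab <- paste0(comp[substr(tri, 3, 3)], "[", comp[r], ">", comp[a], "]",
                    comp[substr(tri, 1, 1)])
    } else {
      lab <- paste0(substr(tri, 1, 1), "[", r, ">", a, "]",
                    substr(tri, 3, 3))
    }
    lab
  }, character(1)))
  for (ctx in names(expect_hand)) {
    expect_equal(prof$count[prof$context == ctx],
                 as.integer(expect_hand[[ctx]]), label = ctx)
  }
  expect_equal(sum(prof$count), nrow(calls))
})

test_that("flanks containing N are skipped with a count", {
  ref <- reference_genome(c(chr1 = "ANCGT"))
  prof <- build_profile(
    tibble::tibble(chrom = "chr1", pos = 3L, ref = "C", alt = "A"), ref)
  expect_equal(sum(prof$count), 0)
  expect_equal(attr(prof, "skipped_n"), 1L)
})

test_that("background selection is seeded, eligible-only and sized", {
  w <- sim_world()
  profs <- purrr::map(w$cohort$samples[1:4], function(s) {
    build_profile(s$truth$variants, w$ref$reference)
  })
  # all eligible controls requested -> all become columns
  all10 <- build_background(profs, n_select = 4, seed = 1)
  expect_equal(ncol(all10), 4)
  expect_equal(colnames(all10), names(profs))
  expect_equal(unname(colSums(all10)), rep(1, 4), tolerance = 1e-12)

  sel1 <- build_background(profs, n_select = 2, seed = 7)
  sel2 <- build_background(profs, n_select = 2, seed = 7)
  expect_identical(sel1, sel2)

  empty <- build_background(profs, n_select = 0, seed = 1)
  expect_equal(ncol(empty), 0)

  # zero-variant controls are ineligible
  zero <- build_profile(tibble::tibble(chrom = character(), pos = integer(),
                                       ref = character(), alt = character()),
                        w$ref$reference)
  expect_error(build_background(c(profs[1], list(z = zero)), n_select = 1),
               NA)
  expect_error(build_background(c(profs[1], list(z = zero)), n_select = 2),
               "eligible")
  expect_error(build_background(list(z = zero), n_select = 1), "eligible")
})

test_that("deconvolution recovers exact mixtures of pool columns", {
  pool <- load_synthetic_pool()
  # identity: a profile equal to one column loads 1 on it
  d <- deconvolute(pool$matrix[, "SYN4"], pool, seed = 1)
  expect_equal(d$contributions$contribution[
    d$contributions$signature == "SYN4"], 1, tolerance = 1e-8)
  expect_equal(d$cosine, 1, tolerance = 1e-9)

  # 0.7 background + 0.3 signature
  mix <- 0.7 * pool$matrix[, "BG1"] + 0.3 * pool$matrix[, "SYN2"]
  d2 <- deconvolute(mix, pool, seed = 1)
  cb <- d2$contributions
  expect_equal(cb$contribution[cb$signature == "BG1"], 0.7, tolerance = 0.02)
  expect_equal(cb$contribution[cb$signature == "SYN2"], 0.3, tolerance = 0.02)
  expect_gt(d2$cosine, 0.999)
  expect_equal(d2$cosmic_total,
               1 - sum(cb$contribution[cb$is_background]), tolerance = 1e-12)
})

test_that("random noiseless mixtures match an independent NNLS oracle", {
  skip_if_not_installed("pracma")
  pool <- load_synthetic_pool()
  A <- pool$matrix
  set.seed(99)
  for (i in 1:20) {
    cols <- sample(ncol(A), 3)
    wts <- stats::runif(3); wts <- wts / sum(wts)
    b <- as.numeric(A[, cols] %*% wts)
    mine <- deconvolute(b, pool, seed = i)
    oracle <- pracma::lsqnonneg(A, b)$x
    oracle <- oracle / sum(oracle)
    expect_equal(mine$contributions$contribution, oracle, tolerance = 1e-4)
  }
})

test_that("deconvolution is invariant to pool column order and drops artifacts", {
  pool <- load_synthetic_pool()
  mix <- 0.5 * pool$matrix[, "SYN1"] + 0.5 * pool$matrix[, "BG2"]
  d1 <- deconvolute(mix, pool, seed = 1)
  perm <- sample(ncol(pool$matrix))
  pool_p <- signature_pool(pool$matrix[, perm],
                           background = c("BG1", "BG2"))
  d2 <- deconvolute(mix, pool_p, seed = 1)
  j <- dplyr::inner_join(d1$contributions, d2$contributions,
                         by = "signature")
  expect_equal(j$contribution.x, j$contribution.y, tolerance = 1e-8)

  # artifact-flagged signatures are removed before fitting
  pool_a <- signature_pool(pool$matrix, background = c("BG1", "BG2"),
                           artifact = "SYN1")
  d3 <- deconvolute(mix, pool_a, seed = 1)
  expect_false("SYN1" %in% d3$contributions$signature)
  expect_equal(sum(d3$contributions$contribution), 1, tolerance = 1e-9)
})

test_that("tidy and glance expose contributions and fit quality", {
  pool <- load_synthetic_pool()
  d <- deconvolute(pool$matrix[, "SYN1"], pool, seed = 1)
  td <- tidy(d)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("signature", "contribution", "is_background"))
  g <- glance(d)
  expect_equal(g$n_signatures, 10)
  expect_equal(g$n_background, 2)
})

test_that("signature pool validation rejects bad matrices", {
  m <- matrix(1 / 96, 96, 2, dimnames = list(sbs96_contexts(), c("a", "b")))
  expect_s3_class(signature_pool(m), "signature_pool")
  m2 <- m; m2[1, 1] <- 2
  expect_error(signature_pool(m2), "sum to 1")
  expect_error(signature_pool(m[1:90, ]), "96 rows")
})
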
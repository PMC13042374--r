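mk_pileup <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    counts[names(r$counts)] <- as.integer(r$counts)
    tibble::tibble(chrom = r$chrom %||% "chr1", pos = r$pos, ref = r$ref,
                   A = counts["A"], C = counts["C"], G = counts["G"],
                   T = counts["T"])
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("candidate calling respects the enzymatic-conversion exclusions", {
  p <- mk_pileup(
    list(pos = 10, ref = "C", counts = c(C = 28, T = 4)),
    list(pos = 20, ref = "C", counts = c(C = 28, A = 4)),
    list(pos = 30, ref = "A", counts = c(A = 30)),
    list(pos = 40, ref = "G", counts = c(G = 25, A = 5)),
    list(pos = 50, ref = "G", counts = c(G = 25, C = 5))
  )
  em <- call_candidates(p, mode = "emseq")
  # C>T and (reverse strand) G>A are ineligible; C>A and G>C are called
  expect_equal(em$pos, c(20, 50))
  expect_equal(em$alt, c("A", "C"))

  wgs <- call_candidates(p, mode = "wgs")
  expect_equal(wgs$pos, c(10, 20, 40, 50))
  expect_error(call_candidates(p[c(2, 1), ]), "sorted")
})

test_that("detection quality equals the exact binomial error tail", {
  # independent oracle: direct summation of the binomial pmf
  tail_oracle <- function(k, n, p) {
    sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
  }
  p <- mk_pileup(list(pos = 5, ref = "A", counts = c(A = 20, G = 10)))
  call <- call_candidates(p, mode = "wgs", error_rate = 1e-3)
  expect_equal(call$qual,
               min(255, -10 * log10(tail_oracle(10, 30, 1e-3 / 3))),
               tolerance = 1e-10)
  # an uncapped case agrees with the oracle exactly
  p2 <- mk_pileup(list(pos = 5, ref = "A", counts = c(A = 27, G = 3)))
  call2 <- call_candidates(p2, mode = "wgs", error_rate = 1e-3)
  expect_equal(call2$qual, -10 * log10(tail_oracle(3, 30, 1e-3 / 3)),
               tolerance = 1e-10)
  # a depth-0 column is skipped, singleton alts score below deep stacks
  expect_equal(nrow(call_candidates(
    mk_pileup(list(pos = 1, ref = "A", counts = c(A = 0))))), 0)
  q1 <- phred_binom_qual(1, 30, 1e-3)
  q10 <- phred_binom_qual(10, 30, 1e-3)
  expect_lt(q1, 30)
  expect_gt(q10, 255 - 1e-9)  # capped
})

test_that("filter cascade applies every rule and matches brute force", {
  res <- filter_resources(
    blacklist = tibble::tibble(chrom = "chr1", start = 900L, end = 1000L),
    population_af = tibble::tibble(
      chrom = "chr1", pos = c(200L, 300L), alt = c("T", "T"),
      af = c(0.002, 0.002)),
    cosmic = tibble::tibble(chrom = "chr1", pos = 300L, alt = "T"),
    autosomes = paste0("chr", 1:22)
  )
  calls <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chrX", "chr1", "chr1", "chr1",
              "chr1", "chr1", "chr1", "chr1", "chr1"),
    pos = c(100L, 200L, 300L, 400L, 500L, 501L, 700L, 800L, 950L,
            1100L, 1200L, 1300L),
    ref = c("A", "C", "C", "A", "A", "A", "A", "A", "A", "A", "AT", "A"),
    alt = c("G", "T", "T", "G", "G", "T", "G", "G", "G", "G", "G", "G"),
    qual = c(50, 50, 50, 50, 50, 50, 29, 30, 50, 50, 50, 50),
    depth = c(30L, 30L, 30L, 30L, 30L, 30L, 30L, 30L, 30L, 200L, 30L, 30L),
    alt_count = 6L,
    n_alt_alleles = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L)
  )
  out <- apply_filter_cascade(calls, res, species = "human")

  flag_of <- function(pos) out$filters[out$pos == pos]
  expect_true(out$retained[out$pos == 100])
  expect_match(flag_of(200), "common_polymorphism")  # AF 0.2%, no rescue
  expect_true(out$retained[out$pos == 300])          # COSMIC rescue
  expect_match(flag_of(400), "non_autosome")
  expect_match(flag_of(500), "continuous")           # adjacent pair:
  expect_match(flag_of(501), "continuous")           # both removed
  expect_match(flag_of(700), "low_qual")             # qual 29 fails,
  expect_true(out$retained[out$pos == 800])          # qual 30 passes
  expect_match(flag_of(950), "blacklist")
  expect_match(flag_of(1100), "high_coverage")       # top-1% coverage
  expect_match(flag_of(1200), "indel")
  expect_match(flag_of(1300), "multiallelic")

  # independent brute-force re-evaluation of each rule per call
  brute <- vapply(seq_len(nrow(calls)), function(i) {
    c0 <- calls[i, ]
    qpass <- calls$qual >= 30  # reference set for distribution-based rules
    cov <- calls$depth[qpass]
    ok <- nchar(c0$ref) == 1 && nchar(c0$alt) == 1
    ok <- ok && c0$chrom %in% paste0("chr", 1:22)
    ok <- ok && c0$n_alt_alleles == 1
    ok <- ok && c0$qual >= 30
    ok <- ok && !any(calls$chrom == c0$chrom & qpass &
                       abs(calls$pos - c0$pos) <= 1 &
                       seq_len(nrow(calls)) != i)
    ok <- ok && !(c0$chrom == "chr1" && c0$pos - 1 >= 900 && c0$pos - 1 < 1000)
    qcut <- stats::quantile(cov, 0.99, names = FALSE)
    ok <- ok && !(c0$depth >= qcut && c0$depth > min(cov))
    af <- 0
    if (c0$pos == 200 && c0$alt == "T") af <- 0.002
    if (c0$pos == 300 && c0$alt == "T") af <- 0.002
    in_cosmic <- c0$pos == 300 && c0$alt == "T"
    ok && !(af > 0.001 && !in_cosmic)
  }, logical(1))
  expect_equal(out$retained, brute)

  # order independence: permuting input order keeps the retained set
  perm <- sample(nrow(calls))
  out_p <- apply_filter_cascade(calls[perm, ], res, species = "human")
  expect_equal(sort(out_p$pos[out_p$retained]), sort(out$pos[out$retained]))

  # every removed call carries at least one flag; retained calls none
  expect_true(all(nchar(out$filters[!out$retained]) > 0))
  expect_true(all(out$filters[out$retained] == ""))
})

test_that("cascade coverage table is honoured and missing loci fail", {
  calls <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L), ref = "A",
                          alt = "G", qual = 50, depth = 30L, alt_count = 5L,
                          n_alt_alleles = 1L)
  res <- filter_resources()
  cov <- tibble::tibble(chrom = "chr1", pos = 10L, coverage = 30)
  expect_error(apply_filter_cascade(calls, res, coverage_by_locus = cov),
               "chr1:20")
})

test_that("paired PBMC/tumor genotypes separate CH from tumor variants", {
  pile <- function(chrom, pos, ref, A = 0, C = 0, G = 0, T = 0) {
    tibble::tibble(chrom = chrom, pos = pos, ref = ref, A = A, C = C,
                   G = G, T = T)
  }
  pbmc <- dplyr::bind_rows(
    pile("chr1", 100, "A", A = 40, G = 5),   # PBMC het, tumor hom -> CH
    pile("chr1", 200, "A", A = 40, G = 2),   # minor support < 3
    pile("chr1", 300, "A", A = 50),          # tumor het, PBMC hom -> tumor
    pile("chr1", 400, "A", A = 20, G = 5)    # coverage < 30 in tumor
  )
  tumor <- dplyr::bind_rows(
    pile("chr1", 100, "A", A = 60),
    pile("chr1", 200, "A", A = 60),
    pile("chr1", 300, "A", A = 30, C = 25),
    pile("chr1", 400, "A", A = 20)
  )
  out <- classify_paired(pbmc, tumor)
  ch <- out[out$origin_class == "CH_derived", ]
  expect_equal(ch$pos, 100)
  expect_equal(ch$allele, "G")
  expect_equal(out$allele[out$pos == 100 & out$origin_class == "germline"],
               "A")
  td <- out[out$origin_class == "tumor_derived", ]
  expect_equal(td$pos, 300)
  expect_equal(td$allele, "C")
  expect_false(200 %in% out$pos)
  expect_false(400 %in% out$pos)
})

test_that("PBMC-only classification selects the 2-30% MAF window", {
  pbmc <- tibble::tibble(
    chrom = "chr1", pos = c(1L, 2L, 3L, 4L), ref = "A",
    A = c(900L, 990L, 600L, 100L), C = 0L, G = 0L,
    T = c(45L, 10L, 400L, 5L)
  )
  out <- classify_pbmc_only(pbmc)
  ch <- out[out$origin_class == "CH_derived", ]
  expect_equal(ch$pos, 1)          # MAF 4.8% in range
  expect_equal(ch$allele, "T")
  expect_false(2 %in% out$pos)     # MAF 1.0% below window
  expect_false(3 %in% out$pos)     # MAF 40% ordinary heterozygote
  expect_false(4 %in% out$pos)     # depth 105 < 300
})

test_that("VCF output carries filter labels and 1-based positions", {
  calls <- tibble::tibble(chrom = "chr1", pos = 42L, ref = "A", alt = "G",
                          qual = 55.5, depth = 30L, alt_count = 6L,
                          n_alt_alleles = 1L,
                          filters = "", retained = TRUE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(calls, path)
  lines <- readLines(path)
  expect_match(lines[1], "VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_match(body, "^chr1\t42\t\\.\tA\tG\t55.50\tPASS")
})
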
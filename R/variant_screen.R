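# Pileup tables are tibbles with columns chrom, pos (1-based), ref and the
# qualified base counts A, C, G, T (already restricted to mapq >= 60,
# baseq >= 30 upstream). depth = A + C + G + T.

BASES <- c("A", "C", "G", "T")

#' Call candidate substitutions from pileup columns
#'
#' For every pileup column the most frequent eligible non-reference allele
#' becomes a candidate call. The detection quality is the phred-scaled exact
#' binomial tail probability of observing at least `alt_count` copies of one
#' specific erroneous base among `depth` qualified bases under a per-base
#' sequencing-error rate `error_rate` (each of the three non-reference bases
#' receiving `error_rate / 3`), capped at 255. In `"emseq"` mode, enzymatic
#' C-to-T conversion makes T unreliable at reference-C columns, so T (and,
#' symmetrically for the reverse strand, A at reference-G columns) is not
#' eligible as an alternate allele.
#'
#' @param pileup Tibble with `chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`,
#'   sorted by (chrom, pos).
#' @param mode `"wgs"` or `"emseq"`.
#' @param error_rate Per-base sequencing error rate epsilon (default 1e-3).
#' @return Tibble of candidate calls: `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `depth`, `alt_count`, `n_alt_alleles` (distinct non-reference alleles
#'   at the column after EM-seq eligibility masking, counting the called
#'   alt plus any other allele supported by at least 2 reads).
#' @export
call_candidates <- function(pileup, mode = c("wgs", "emseq"),
                            error_rate = 1e-3) {
  mode <- match.arg(mode)
  pileup <- tibble::as_tibble(pileup)
  stopifnot(all(c("chrom", "pos", "ref", BASES) %in% names(pileup)))
  if (nrow(pileup) > 1) {
    o <- order(pileup$chrom, pileup$pos)
    if (!identical(o, seq_len(nrow(pileup)))) {
      stop("pileup must be sorted by (chrom, pos)")
    }
  }
  counts <- as.matrix(pileup[, BASES])
  storage.mode(counts) <- "integer"
  depth <- rowSums(counts)
  ref_idx <- match(pileup$ref, BASES)
  if (anyNA(ref_idx)) stop("ref_base must be one of A/C/G/T")

  nonref <- counts
  nonref[cbind(seq_len(nrow(counts)), ref_idx)] <- 0L

  eligible <- nonref
  if (mode == "emseq") {
    eligible[pileup$ref == "C", match("T", BASES)] <- 0L
    eligible[pileup$ref == "G", match("A", BASES)] <- 0L
  }
  alt_idx <- max.col(eligible, ties.method = "first")
  alt_count <- eligible[cbind(seq_len(nrow(eligible)), alt_idx)]
  keep <- depth > 0L & alt_count > 0L
  # distinct non-reference alleles at the locus: the called alt plus any
  # other eligible allele with >= 2 supporting reads (a single stray read
  # is an error observation, not an allele)
  n_alt_alleles <- pmax(rowSums(eligible >= 2L), 1L)

  out <- tibble::tibble(
    chrom = pileup$chrom[keep],
    pos = pileup$pos[keep],
    ref = pileup$ref[keep],
    alt = BASES[alt_idx[keep]],
    depth = as.integer(depth[keep]),
    alt_count = as.integer(alt_count[keep]),
    n_alt_alleles = as.integer(n_alt_alleles[keep])
  )
  out$qual <- phred_binom_qual(out$alt_count, out$depth, error_rate)
  out[, c("chrom", "pos", "ref", "alt", "qual", "depth", "alt_count",
          "n_alt_alleles")]
}

#' Phred-scaled binomial error-only tail probability
#'
#' `-10 log10 P(X >= k)` with `X ~ Binomial(n, error_rate / 3)`, capped at
#' 255. This is the detection-quality score attached to candidate calls.
#'
#' @param k Alternate-allele count(s).
#' @param n Depth(s).
#' @param error_rate Per-base error rate epsilon; each specific wrong base
#'   occurs at `error_rate / 3`.
#' @return Numeric vector of phred scores.
#' @export
phred_binom_qual <- function(k, n, error_rate = 1e-3) {
  logp <- stats::pbinom(k - 1, n, error_rate / 3, lower.tail = FALSE,
                        log.p = TRUE)
  q <- -10 * logp / log(10)
  pmin(q, 255)
}

#' Assemble resources for the variant filter cascade
#'
#' @param blacklist Tibble of problematic intervals (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. ENCODE-style excluded regions.
#' @param population_af Tibble (`chrom`, `pos`, `alt`, `af`) with the maximum
#'   population allele frequency across databases per allele.
#' @param cosmic Tibble (`chrom`, `pos`, `alt`) of cancer-associated alleles
#'   that rescue a call from the population-frequency filter.
#' @param autosomes Character vector of autosomal chromosome names. Calls on
#'   other chromosomes (sex chromosomes, mitochondria) are removed.
#' @param min_qual Detection-quality threshold; calls strictly below are
#'   removed (default 30).
#' @param max_af Population-frequency threshold; alleles with frequency
#'   strictly greater are removed unless rescued (default 0.001, i.e. 0.1%).
#' @param adjacency_window Candidates within this many bp of another
#'   candidate are removed as continuous variants (default 1 = immediately
#'   adjacent positions).
#' @param coverage_quantile_cut Fraction of top-coverage candidate loci to
#'   discard: 0.01 for human, 0.10 for mouse.
#' @param cosmic_rescue If `TRUE` (default) COSMIC membership overrides the
#'   population-frequency filter; set `FALSE` to disable the rescue.
#' @return A `filter_resources` list.
#' @export
filter_resources <- function(blacklist = NULL, population_af = NULL,
                             cosmic = NULL,
                             autosomes = paste0("chr", 1:22),
                             min_qual = 30, max_af = 0.001,
                             adjacency_window = 1L,
                             coverage_quantile_cut = 0.01,
                             cosmic_rescue = TRUE) {
  stopifnot(coverage_quantile_cut > 0, coverage_quantile_cut < 1)
  empty_iv <- tibble::tibble(chrom = character(), start = integer(),
                             end = integer())
  empty_af <- tibble::tibble(chrom = character(), pos = integer(),
                             alt = character(), af = numeric())
  empty_cos <- tibble::tibble(chrom = character(), pos = integer(),
                              alt = character())
  structure(list(
    blacklist = if (is.null(blacklist)) empty_iv else tibble::as_tibble(blacklist),
    population_af = if (is.null(population_af)) empty_af else tibble::as_tibble(population_af),
    cosmic = if (is.null(cosmic)) empty_cos else tibble::as_tibble(cosmic),
    autosomes = autosomes,
    min_qual = min_qual,
    max_af = max_af,
    adjacency_window = as.integer(adjacency_window),
    coverage_quantile_cut = coverage_quantile_cut,
    cosmic_rescue = isTRUE(cosmic_rescue)
  ), class = "filter_resources")
}

#' Apply the somatic-variant filter cascade
#'
#' Retains substitutions that are autosomal, biallelic at their locus, of
#' detection quality >= 30, not adjacent to another candidate (continuous
#' variants), outside the blacklist, below the top-coverage quantile of
#' candidate loci (top 1% for human, top 10% for mouse), and either rare in
#' population databases (allele frequency <= 0.1%) or recorded as a
#' cancer-associated COSMIC allele. Filters are evaluated independently, so
#' the retained set does not depend on application order; every removed call
#' lists all filters it failed. The adjacency and coverage-quantile rules
#' take quality-passing candidates (`qual >= min_qual`) as their reference
#' population: single-read observation sites below the detection-quality
#' bar are error noise, not variants.
#'
#' @param calls Candidate-call tibble from [call_candidates()]; indels may be
#'   represented with multi-base `ref`/`alt`.
#' @param resources A [filter_resources()] object.
#' @param coverage_by_locus Optional tibble (`chrom`, `pos`, `coverage`)
#'   giving locus coverage; defaults to the calls' own `depth`. Missing a
#'   call's locus is an error.
#' @param species `"human"` (top-1% coverage cut) or `"mouse"` (top 10%);
#'   overrides `resources$coverage_quantile_cut`.
#' @return The input tibble with `filters` (comma-separated labels, `""` when
#'   retained) and `retained` (logical) columns appended.
#' @export
apply_filter_cascade <- function(calls, resources,
                                 coverage_by_locus = NULL,
                                 species = c("human", "mouse")) {
  species <- match.arg(species)
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) {
    calls$filters <- character(0)
    calls$retained <- logical(0)
    return(calls)
  }
  # mouse data use the deeper top-10% cut; otherwise the resources value
  cut <- if (species == "mouse") 0.10 else resources$coverage_quantile_cut

  if (is.null(coverage_by_locus)) {
    coverage <- calls$depth
  } else {
    m <- dplyr::left_join(
      calls[, c("chrom", "pos")], tibble::as_tibble(coverage_by_locus),
      by = c("chrom", "pos")
    )
    if (anyNA(m$coverage)) {
      bad <- which(is.na(m$coverage))[1]
      stop("no coverage for locus ", calls$chrom[bad], ":", calls$pos[bad])
    }
    coverage <- m$coverage
  }

  flags <- vector("list", nrow(calls))
  add_flag <- function(which, label) {
    for (i in which(which)) flags[[i]] <<- c(flags[[i]], label)
    invisible(NULL)
  }

  add_flag(nchar(calls$ref) != 1 | nchar(calls$alt) != 1, "indel")
  add_flag(!(calls$chrom %in% resources$autosomes), "non_autosome")
  if ("n_alt_alleles" %in% names(calls)) {
    add_flag(calls$n_alt_alleles > 1, "multiallelic")
  }
  add_flag(calls$qual < resources$min_qual, "low_qual")

  # reference population for the distribution-based rules: candidates that
  # pass the detection-quality bar (raw single-read observation sites are
  # error noise, not variants); keeps the cascade order-independent since
  # qual is intrinsic to each call
  qok <- calls$qual >= resources$min_qual

  # continuous variants: any other quality-passing candidate within the
  # adjacency window
  adjacent <- vapply(seq_len(nrow(calls)), function(i) {
    same <- calls$chrom == calls$chrom[i]
    any(same & qok & abs(calls$pos - calls$pos[i]) <= resources$adjacency_window &
          seq_len(nrow(calls)) != i)
  }, logical(1))
  add_flag(adjacent, "continuous")

  bl <- resources$blacklist
  if (nrow(bl) > 0) {
    in_bl <- vapply(seq_len(nrow(calls)), function(i) {
      p0 <- calls$pos[i] - 1L  # 0-based
      any(bl$chrom == calls$chrom[i] & bl$start <= p0 & p0 < bl$end)
    }, logical(1))
    add_flag(in_bl, "blacklist")
  }

  # top-coverage cut over quality-passing candidate loci: retain strictly
  # below the (1 - cut) quantile of their coverages; loci tied with the
  # minimum never fail (guards the all-equal-coverage degenerate case)
  cov_ref <- if (any(qok)) coverage[qok] else coverage
  cov_cut <- stats::quantile(cov_ref, probs = 1 - cut, names = FALSE,
                             type = 7)
  add_flag(coverage >= cov_cut & coverage > min(cov_ref), "high_coverage")

  af <- resources$population_af
  pop_af <- rep(0, nrow(calls))
  if (nrow(af) > 0) {
    m <- dplyr::left_join(calls[, c("chrom", "pos", "alt")], af,
                          by = c("chrom", "pos", "alt"))
    pop_af <- ifelse(is.na(m$af), 0, m$af)
  }
  in_cosmic <- rep(FALSE, nrow(calls))
  if (nrow(resources$cosmic) > 0) {
    key <- paste(calls$chrom, calls$pos, calls$alt)
    ckey <- paste(resources$cosmic$chrom, resources$cosmic$pos,
                  resources$cosmic$alt)
    in_cosmic <- key %in% ckey
  }
  common <- pop_af > resources$max_af
  if (resources$cosmic_rescue) common <- common & !in_cosmic
  add_flag(common, "common_polymorphism")

  calls$filters <- vapply(flags, function(f) paste(f, collapse = ","),
                          character(1))
  calls$retained <- calls$filters == ""
  calls
}

#' Retained calls only
#'
#' Convenience accessor returning the rows of a filtered call set that
#' passed every filter.
#'
#' @param calls Output of [apply_filter_cascade()].
#' @return Tibble of retained calls.
#' @export
retained_calls <- function(calls) {
  dplyr::filter(calls, .data$retained)
}

# classify one locus's counts: major/minor allele and counts
locus_major_minor <- function(counts) {
  o <- order(counts, decreasing = TRUE)
  list(major = BASES[o[1]], minor = BASES[o[2]],
       major_n = counts[o[1]], minor_n = counts[o[2]])
}

#' Classify variants from paired PBMC and tumor genotypes
#'
#' Loci heterozygous in PBMCs (minor allele supported by at least
#' `min_minor_reads` reads) but homozygous in the paired tumor yield
#' clonal-hematopoiesis-derived minor alleles; loci heterozygous in tumor
#' but homozygous in PBMCs yield tumor-derived minor alleles. Major alleles
#' are reported as germline. Only loci covered at `min_coverage` or more in
#' both samples enter the comparison (counts are assumed pre-filtered to
#' mapping and base quality >= 20); a locus is treated as homozygous when
#' its minor allele has fewer than `min_minor_reads` supporting reads.
#'
#' @param pbmc,tumor Pileup tibbles (`chrom`, `pos`, `ref`, `A`, `C`, `G`,
#'   `T`) for the two tissues.
#' @param min_coverage Minimum depth in both samples (default 30).
#' @param min_minor_reads Reads supporting a heterozygous minor allele
#'   (default 3).
#' @return Tibble `chrom`, `pos`, `ref`, `allele`, `origin_class` in
#'   \{CH_derived, tumor_derived, germline\}; the `skipped_unpaired`
#'   attribute counts loci present in only one map.
#' @export
classify_paired <- function(pbmc, tumor, min_coverage = 30,
                            min_minor_reads = 3) {
  pbmc <- tibble::as_tibble(pbmc)
  tumor <- tibble::as_tibble(tumor)
  j <- dplyr::inner_join(pbmc, tumor, by = c("chrom", "pos", "ref"),
                         suffix = c("_p", "_t"))
  skipped <- (nrow(pbmc) - nrow(j)) + (nrow(tumor) - nrow(j))
  out <- list()
  for (i in seq_len(nrow(j))) {
    cp <- c(A = j$A_p[i], C = j$C_p[i], G = j$G_p[i], T = j$T_p[i])
    ct <- c(A = j$A_t[i], C = j$C_t[i], G = j$G_t[i], T = j$T_t[i])
    if (sum(cp) < min_coverage || sum(ct) < min_coverage) next
    p <- locus_major_minor(cp)
    t <- locus_major_minor(ct)
    p_het <- p$minor_n >= min_minor_reads
    t_het <- t$minor_n >= min_minor_reads
    if (p_het && !t_het) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = j$chrom[i], pos = j$pos[i], ref = j$ref[i],
        allele = c(p$minor, p$major),
        origin_class = c("CH_derived", "germline")
      )
    } else if (t_het && !p_het) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = j$chrom[i], pos = j$pos[i], ref = j$ref[i],
        allele = c(t$minor, t$major),
        origin_class = c("tumor_derived", "germline")
      )
    }
  }
  res <- if (length(out) > 0) dplyr::bind_rows(out) else tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    allele = character(), origin_class = character()
  )
  attr(res, "skipped_unpaired") <- skipped
  res
}

#' Classify clonal-hematopoiesis variants from PBMC genotypes alone
#'
#' When only the white-blood-cell compartment is genotyped, deeply covered
#' loci (>= `min_coverage`, default 300-fold) whose minor allele frequency
#' lies within `maf_range` (default 2-30%) are labelled clonal-hematopoiesis
#' derived; loci near 50% are ordinary heterozygotes and stay unclassified.
#'
#' @param pbmc Pileup tibble (`chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`),
#'   pre-filtered to mapping/base quality >= 20.
#' @param min_coverage Minimum locus depth (default 300).
#' @param maf_range Inclusive minor-allele-frequency window (default
#'   `c(0.02, 0.30)`).
#' @return Tibble as in [classify_paired()].
#' @export
classify_pbmc_only <- function(pbmc, min_coverage = 300,
                               maf_range = c(0.02, 0.30)) {
  pbmc <- tibble::as_tibble(pbmc)
  out <- list()
  for (i in seq_len(nrow(pbmc))) {
    cp <- c(A = pbmc$A[i], C = pbmc$C[i], G = pbmc$G[i], T = pbmc$T[i])
    depth <- sum(cp)
    if (depth < min_coverage) next
    p <- locus_major_minor(cp)
    maf <- p$minor_n / depth
    if (maf >= maf_range[1] && maf <= maf_range[2]) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = pbmc$chrom[i], pos = pbmc$pos[i], ref = pbmc$ref[i],
        allele = c(p$minor, p$major),
        origin_class = c("CH_derived", "germline")
      )
    }
  }
  if (length(out) > 0) dplyr::bind_rows(out) else tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    allele = character(), origin_class = character()
  )
}

#' Write calls as a minimal VCF 4.2
#'
#' The FILTER column carries the cascade's flag labels (`PASS` when
#' retained). Positions are emitted 1-based per the VCF convention.
#'
#' @param calls Output of [apply_filter_cascade()] (or [call_candidates()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Qualified depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt allele count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  filt <- if ("filters" %in% names(calls)) {
    ifelse(calls$filters == "", "PASS", gsub(",", ";", calls$filters))
  } else rep(".", nrow(calls))
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\t%s\tDP=%d;AC=%d",
                   calls$chrom, calls$pos, calls$ref, calls$alt, calls$qual,
                   filt, calls$depth, calls$alt_count)
  writeLines(lines, con)
  invisible(path)
}

#' Build a pileup table from fragments and their base calls
#'
#' Tallies qualified base observations per locus. Depth at a locus is the
#' number of overlapping fragments; fragments without an explicit base call
#' at the locus are counted as reference observations (sparse base-call
#' storage: only non-reference observations and calls at loci of interest
#' need be materialised).
#'
#' @param fragments Fragment tibble.
#' @param base_calls Tibble (`fragment_id`, `chrom`, `pos` (1-based),
#'   `base`, `qual`).
#' @param reference A [reference_genome()].
#' @param loci Optional tibble (`chrom`, `pos`) restricting output; default:
#'   every locus carrying at least one non-reference observation.
#' @param min_baseq Base-quality threshold (default 30).
#' @return Pileup tibble (`chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`) sorted
#'   by (chrom, pos).
#' @export
pileup_from_fragments <- function(fragments, base_calls, reference,
                                  loci = NULL, min_baseq = 30) {
  fragments <- as_fragments(fragments)
  base_calls <- tibble::as_tibble(base_calls)
  if (!"qual" %in% names(base_calls)) base_calls$qual <- 60L
  base_calls <- dplyr::filter(base_calls, .data$qual >= min_baseq)
  seq_cache <- new.env(parent = emptyenv())
  chrom_string <- function(ch) {
    if (is.null(seq_cache[[ch]])) {
      seq_cache[[ch]] <- as.character(reference$seq[[ch]])
    }
    seq_cache[[ch]]
  }
  refbase <- function(chrom, pos) {
    # pos is 1-based
    out <- character(length(chrom))
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      out[sel] <- substring(chrom_string(ch), pos[sel], pos[sel])
    }
    out
  }
  if (is.null(loci)) {
    bc_ref <- refbase(base_calls$chrom, base_calls$pos)
    loci <- dplyr::distinct(
      base_calls[base_calls$base != bc_ref, c("chrom", "pos")]
    )
  } else {
    loci <- dplyr::distinct(tibble::as_tibble(loci)[, c("chrom", "pos")])
  }
  if (nrow(loci) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), A = integer(), C = integer(),
                          G = integer(), T = integer()))
  }
  loci$ref <- refbase(loci$chrom, loci$pos)

  # explicit observations at the loci
  obs <- dplyr::inner_join(base_calls, loci, by = c("chrom", "pos"))
  tallies <- obs %>%
    dplyr::count(.data$chrom, .data$pos, .data$base) %>%
    tidyr::pivot_wider(names_from = "base", values_from = "n",
                       values_fill = 0L)
  for (b in BASES) if (!b %in% names(tallies)) tallies[[b]] <- 0L

  # fragments overlapping each locus without an explicit call => reference
  n_overlap <- vapply(seq_len(nrow(loci)), function(i) {
    p0 <- loci$pos[i] - 1L
    sum(fragments$chrom == loci$chrom[i] & fragments$start <= p0 &
          p0 < fragments$end)
  }, integer(1))
  n_called <- obs %>% dplyr::count(.data$chrom, .data$pos, name = "n_called")

  out <- loci %>%
    dplyr::left_join(tallies[, c("chrom", "pos", BASES)],
                     by = c("chrom", "pos")) %>%
    dplyr::left_join(n_called, by = c("chrom", "pos")) %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(c(BASES, "n_called")),
                                ~ tidyr::replace_na(.x, 0L)))
  out$n_uncalled <- pmax(n_overlap - out$n_called, 0L)
  for (b in BASES) {
    sel <- out$ref == b
    out[[b]][sel] <- out[[b]][sel] + out$n_uncalled[sel]
  }
  out %>%
    dplyr::select("chrom", "pos", "ref", dplyr::all_of(BASES)) %>%
    dplyr::arrange(.data$chrom, .data$pos)
}
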
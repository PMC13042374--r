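# Allele-aware fragmentomics: partition fragments at variant loci into
# Mut-DNA (variant allele) and Wt-DNA (reference allele), then contrast
# size, end-motif, end-position and nucleosome-context statistics.

#' Partition fragments by carried allele at variant loci
#'
#' A fragment overlapping exactly one retained variant locus is assigned to
#' Mut-DNA when its base call at that locus equals the variant allele and to
#' Wt-DNA when it equals the reference allele. Fragments spanning two or
#' more variant loci are excluded (counted in `excluded_multi`); fragments
#' with no base call at their locus, or carrying a third allele, are dropped
#' with counts.
#'
#' @param fragments Fragment tibble.
#' @param base_calls Tibble (`fragment_id`, `chrom`, `pos` (1-based),
#'   `base`).
#' @param loci Retained variant calls (`chrom`, `pos`, `ref`, `alt`).
#' @return An `allele_partition`: list with `mut` and `wt` fragment tibbles
#'   (each gaining a `locus` column `chrom:pos`), and counts
#'   `excluded_multi`, `dropped_no_call`, `dropped_other_allele`.
#' @export
partition_by_allele <- function(fragments, base_calls, loci) {
  fragments <- as_fragments(fragments)
  loci <- tibble::as_tibble(loci)
  base_calls <- tibble::as_tibble(base_calls)

  # overlap count per fragment across all variant loci
  n_loci <- integer(nrow(fragments))
  hit_locus <- integer(nrow(fragments))  # row of `loci` for single-hit frags
  for (j in seq_len(nrow(loci))) {
    p0 <- loci$pos[j] - 1L
    ov <- fragments$chrom == loci$chrom[j] & fragments$start <= p0 &
      p0 < fragments$end
    n_loci <- n_loci + ov
    hit_locus[ov] <- j
  }
  excluded_multi <- sum(n_loci >= 2)
  single <- which(n_loci == 1L)

  if (length(single) > 0) {
    frag1 <- fragments[single, , drop = FALSE]
    li <- hit_locus[single]
    key <- paste(frag1$fragment_id, loci$chrom[li], loci$pos[li])
    bc_key <- paste(base_calls$fragment_id, base_calls$chrom, base_calls$pos)
    base_at <- base_calls$base[match(key, bc_key)]
    is_mut <- !is.na(base_at) & base_at == loci$alt[li]
    is_wt <- !is.na(base_at) & base_at == loci$ref[li]
    frag1$locus <- paste0(loci$chrom[li], ":", loci$pos[li])
    mut <- frag1[is_mut, , drop = FALSE]
    wt <- frag1[is_wt, , drop = FALSE]
    dropped_no_call <- sum(is.na(base_at))
    dropped_other <- sum(!is.na(base_at) & !is_mut & !is_wt)
  } else {
    mut <- wt <- fragments[0, , drop = FALSE]
    mut$locus <- wt$locus <- character(0)
    dropped_no_call <- dropped_other <- 0L
  }
  structure(list(
    mut = tibble::as_tibble(mut),
    wt = tibble::as_tibble(wt),
    excluded_multi = excluded_multi,
    dropped_no_call = dropped_no_call,
    dropped_other_allele = dropped_other
  ), class = "allele_partition")
}

#' @export
print.allele_partition <- function(x, ...) {
  cat("<allele_partition> Mut-DNA: ", nrow(x$mut), " fragments, Wt-DNA: ",
      nrow(x$wt), " fragments (", x$excluded_multi,
      " multi-locus excluded)\n", sep = "")
  invisible(x)
}

#' Fraction of short fragments
#'
#' cfDNA molecules of length `max_len` bp or shorter (default 150, inclusive)
#' count as short.
#'
#' @param fragments Fragment tibble.
#' @param max_len Inclusive short-fragment cutoff in bp.
#' @return Fraction in \[0,1\]; `NA` (undefined) for an empty set.
#' @export
frac_short <- function(fragments, max_len = 150) {
  if (nrow(fragments) == 0) return(NA_real_)
  fragments <- as_fragments(fragments)
  mean(fragments$length <= max_len)
}

# fetch reference subsequence [start0, start0+width) on the forward strand;
# NA when out of bounds
ref_kmer <- function(reference, chrom, start0, width) {
  out <- rep(NA_character_, length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s <- reference$seq[[ch]]
    if (is.null(s)) next
    len <- length(s)
    ok <- sel & start0 >= 0 & (start0 + width) <= len
    if (any(ok)) {
      v <- Biostrings::Views(s, start = start0[ok] + 1L,
                             width = width)
      out[ok] <- as.character(v)
    }
  }
  out
}

revcomp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

all_4mers <- function() {
  g <- expand.grid(b4 = BASES, b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3, g$b4))
}

tally_motifs <- function(motifs) {
  lv <- all_4mers()
  motifs <- motifs[!is.na(motifs) & motifs %in% lv]
  tab <- table(factor(motifs, levels = lv))
  n <- sum(tab)
  tibble::tibble(
    motif = lv,
    count = as.integer(tab),
    freq = if (n > 0) as.integer(tab) / n else rep(0, 256)
  )
}

#' 5'-end 4-mer motif spectrum
#'
#' Each fragment contributes two motifs, one per end, read 5'->3' on the
#' strand whose 5' terminus that end is: the reference 4-mer starting at the
#' upstream (U) end on the forward strand, and the reverse complement of the
#' reference 4-mer ending at the downstream (D) end. Motifs are taken from
#' the reference sequence at the fragment coordinates, not from read bases.
#' Ends too close to a contig edge are skipped (counted in the `n_skipped`
#' attribute).
#'
#' @param fragments Fragment tibble.
#' @param reference A [reference_genome()].
#' @return Tibble (`motif`, `count`, `freq`) over all 256 4-mers, with
#'   attributes `n_ends` and `n_skipped`.
#' @export
end_motifs <- function(fragments, reference) {
  fragments <- as_fragments(fragments)
  u <- ref_kmer(reference, fragments$chrom, fragments$u_end, 4L)
  d_fwd <- ref_kmer(reference, fragments$chrom, fragments$d_end - 3L, 4L)
  d <- rep(NA_character_, length(d_fwd))
  ok <- !is.na(d_fwd)
  d[ok] <- revcomp_vec(d_fwd[ok])
  motifs <- c(u, d)
  out <- tally_motifs(motifs)
  attr(out, "n_ends") <- sum(!is.na(motifs))
  attr(out, "n_skipped") <- sum(is.na(motifs))
  out
}

#' Breakpoint 4-mer motif spectrum
#'
#' Per fragment end: the two reference bases immediately outside the
#' fragment concatenated with the first two bases inside, strand-oriented as
#' in [end_motifs()]. The canonical CT-5'-CC motif is the entry `"CTCC"`:
#' genomic CT before the cut, fragment CC after it.
#'
#' @inheritParams end_motifs
#' @return As [end_motifs()].
#' @export
breakpoint_motifs <- function(fragments, reference) {
  fragments <- as_fragments(fragments)
  u <- ref_kmer(reference, fragments$chrom, fragments$u_end - 2L, 4L)
  d_fwd <- ref_kmer(reference, fragments$chrom, fragments$d_end - 1L, 4L)
  d <- rep(NA_character_, length(d_fwd))
  ok <- !is.na(d_fwd)
  d[ok] <- revcomp_vec(d_fwd[ok])
  motifs <- c(u, d)
  out <- tally_motifs(motifs)
  attr(out, "n_ends") <- sum(!is.na(motifs))
  attr(out, "n_skipped") <- sum(is.na(motifs))
  out
}

#' Fraction of a given motif in a motif spectrum
#'
#' @param motif_tbl Output of [end_motifs()] or [breakpoint_motifs()].
#' @param motif 4-mer, e.g. `"CCCA"` or `"CTCC"`.
#' @return The frequency of that motif.
#' @export
motif_fraction <- function(motif_tbl, motif) {
  motif_tbl$freq[match(motif, motif_tbl$motif)]
}

#' Motif diversity score
#'
#' Shannon entropy of the 256-motif frequency vector normalized by
#' `ln(256)`, so 1 marks the uniform (most random) spectrum and 0 a
#' single-motif spectrum.
#'
#' @param freqs A 256-vector of frequencies summing to 1, or a motif tibble
#'   from [end_motifs()]/[breakpoint_motifs()].
#' @return Score in \[0,1\].
#' @export
motif_diversity <- function(freqs) {
  if (is.data.frame(freqs)) freqs <- freqs$freq
  if (any(freqs < 0)) stop("motif frequencies must be nonnegative")
  p <- freqs[freqs > 0]
  -sum(p * log(p)) / log(256)
}

#' Build a panel end-distribution model
#'
#' Tallies, per genomic position, how often fragments of a healthy-control
#' panel terminate there, keeping upstream (U) and downstream (D) ends in
#' separate orientation-aware tallies. The `scale` slot (ends-per-million,
#' `1e6 / total_ends`) makes E-index values comparable across panels of
#' different depths.
#'
#' @param panel_fragments Fragment tibble from the control panel.
#' @return An `end_model`: list with `counts` (tibble `chrom`, `pos`,
#'   `u_count`, `d_count`), `total_ends`, `scale`.
#' @export
build_end_model <- function(panel_fragments) {
  if (nrow(panel_fragments) == 0) stop("panel is empty")
  panel_fragments <- as_fragments(panel_fragments)
  u <- panel_fragments %>%
    dplyr::count(.data$chrom, pos = .data$u_end, name = "u_count")
  d <- panel_fragments %>%
    dplyr::count(.data$chrom, pos = .data$d_end, name = "d_count")
  counts <- dplyr::full_join(u, d, by = c("chrom", "pos")) %>%
    dplyr::mutate(
      u_count = dplyr::coalesce(.data$u_count, 0L),
      d_count = dplyr::coalesce(.data$d_count, 0L)
    ) %>%
    dplyr::arrange(.data$chrom, .data$pos)
  total <- 2L * nrow(panel_fragments)
  structure(list(counts = counts, total_ends = total, scale = 1e6 / total),
            class = "end_model")
}

#' @export
print.end_model <- function(x, ...) {
  cat("<end_model> ", x$total_ends, " panel ends over ", nrow(x$counts),
      " positions (scale ", format(x$scale, digits = 4),
      " per million)\n", sep = "")
  invisible(x)
}

#' Write / read an end model as TSV
#'
#' @param model An `end_model`.
#' @param path TSV path (`chrom`, `pos`, `u_count`, `d_count`).
#' @return `path` / an `end_model`.
#' @export
write_end_model <- function(model, path) {
  readr::write_tsv(model$counts, path)
  invisible(path)
}

#' @rdname write_end_model
#' @export
read_end_model <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  total <- sum(counts$u_count) + sum(counts$d_count)
  structure(list(counts = counts, total_ends = total, scale = 1e6 / total),
            class = "end_model")
}

#' E-index: consistency of fragment ends with a panel end model
#'
#' For each fragment, its U-end position is looked up in the panel's U-end
#' tally and its D-end position in the D-end tally; the E-index is the mean
#' over fragments of the summed counts, `(1/N) * sum_i (M_U(i) + M_D(i))`.
#' Positions absent from the model contribute zero. By default the panel
#' counts are normalized to ends-per-million (the model's `scale`); set
#' `normalized = FALSE` for raw panel counts.
#'
#' @param fragments Fragment tibble (the working sample, e.g. Mut-DNA).
#' @param model An [build_end_model()] result.
#' @param normalized Use ends-per-million panel counts (default `TRUE`).
#' @return Nonnegative E-index; `NA` for an empty fragment set.
#' @export
e_index <- function(fragments, model, normalized = TRUE) {
  if (nrow(fragments) == 0) return(NA_real_)
  fragments <- as_fragments(fragments)
  key_u <- paste(fragments$chrom, fragments$u_end)
  key_d <- paste(fragments$chrom, fragments$d_end)
  model_key <- paste(model$counts$chrom, model$counts$pos)
  mu <- model$counts$u_count[match(key_u, model_key)]
  md <- model$counts$d_count[match(key_d, model_key)]
  mu[is.na(mu)] <- 0
  md[is.na(md)] <- 0
  s <- if (normalized) model$scale else 1
  mean(s * (mu + md))
}

#' Fraction of fragment ends within +/- 50 bp of nucleosome centers
#'
#' Each U and each D end is matched to its nearest nucleosome center on the
#' same chromosome (ties broken toward the smaller coordinate); the signed
#' distance is end minus center (negative when the end lies upstream of the
#' center). The headline statistic is the percentage of ends whose absolute
#' distance is at most `window` bp (inclusive).
#'
#' @param fragments Fragment tibble.
#' @param nucleosome_centers Tibble (`chrom`, `center`) of 0-based center
#'   positions (see [read_nucleosome_track()]).
#' @param window Half-width in bp (default 50).
#' @return List with `fraction` (percentage in \[0,100\]), `distances`
#'   (tibble `chrom`, `pos`, `end_type`, `distance`) and `excluded` (ends on
#'   chromosomes lacking centers).
#' @export
nucleosome_end_fraction <- function(fragments, nucleosome_centers,
                                    window = 50) {
  fragments <- as_fragments(fragments)
  centers <- tibble::as_tibble(nucleosome_centers) %>%
    dplyr::arrange(.data$chrom, .data$center)
  ends <- dplyr::bind_rows(
    tibble::tibble(chrom = fragments$chrom, pos = fragments$u_end,
                   end_type = "U"),
    tibble::tibble(chrom = fragments$chrom, pos = fragments$d_end,
                   end_type = "D")
  )
  ends$distance <- NA_real_
  for (ch in unique(ends$chrom)) {
    cc <- centers$center[centers$chrom == ch]
    sel <- ends$chrom == ch
    if (length(cc) == 0) next
    p <- ends$pos[sel]
    idx <- findInterval(p, cc)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(cc))
    d_lo <- abs(p - cc[lo])
    d_hi <- abs(p - cc[hi])
    # tie -> smaller coordinate (lo)
    nearest <- ifelse(d_lo <= d_hi, cc[lo], cc[hi])
    ends$distance[sel] <- p - nearest
  }
  excluded <- sum(is.na(ends$distance))
  kept <- ends[!is.na(ends$distance), , drop = FALSE]
  fraction <- if (nrow(kept) == 0) NA_real_ else {
    100 * mean(abs(kept$distance) <= window)
  }
  list(fraction = fraction, distances = kept, excluded = excluded)
}

#' Mut-minus-Wt difference of a per-class statistic
#'
#' @param metric_mut,metric_wt The statistic evaluated on Mut-DNA and
#'   Wt-DNA fragments.
#' @return `metric_mut - metric_wt`; `NA` when either operand is undefined.
#' @export
diff_metric <- function(metric_mut, metric_wt) {
  ifelse(is.na(metric_mut) | is.na(metric_wt), NA_real_,
         metric_mut - metric_wt)
}

#' Summarise fragmentomic statistics for one fragment set
#'
#' Convenience wrapper computing the per-class statistics feeding the
#' Diff-* features: fragment count, short-fragment fraction, CCCA end-motif
#' and CT-5'-CC breakpoint-motif fractions, both motif diversity scores,
#' E-index and the nucleosome end fraction.
#'
#' @param fragments Fragment tibble.
#' @param reference A [reference_genome()].
#' @param end_model Optional [build_end_model()] result.
#' @param nucleosome_centers Optional center tibble.
#' @return One-row tibble: `n`, `frac_short`, `frac_ccca`, `frac_ctcc`,
#'   `mds_end`, `mds_breakpoint`, `e_index`, `frac_ends_in_nucleosome`.
#' @export
fragment_summary <- function(fragments, reference, end_model = NULL,
                             nucleosome_centers = NULL) {
  if (nrow(fragments) == 0) {
    return(tibble::tibble(
      n = 0L, frac_short = NA_real_, frac_ccca = NA_real_,
      frac_ctcc = NA_real_, mds_end = NA_real_, mds_breakpoint = NA_real_,
      e_index = NA_real_, frac_ends_in_nucleosome = NA_real_
    ))
  }
  em <- end_motifs(fragments, reference)
  bm <- breakpoint_motifs(fragments, reference)
  tibble::tibble(
    n = nrow(fragments),
    frac_short = frac_short(fragments),
    frac_ccca = motif_fraction(em, "CCCA"),
    frac_ctcc = motif_fraction(bm, "CTCC"),
    mds_end = motif_diversity(em),
    mds_breakpoint = motif_diversity(bm),
    e_index = if (is.null(end_model)) NA_real_ else e_index(fragments, end_model),
    frac_ends_in_nucleosome = if (is.null(nucleosome_centers)) NA_real_ else {
      nucleosome_end_fraction(fragments, nucleosome_centers)$fraction
    }
  )
}

#' Mut-vs-Wt difference features for one sample
#'
#' Computes the per-class fragmentomic summaries for both halves of an
#' allele partition and returns the Mut-minus-Wt contrasts, optionally
#' joined by the gene-body methylation difference.
#'
#' @param partition An [partition_by_allele()] result.
#' @inheritParams fragment_summary
#' @param diff_methylation_gene_body Optional precomputed gene-body
#'   Diff-methylation value (percentage points).
#' @return One-row tibble: `diff_size`, `diff_ccca`, `diff_ctcc`,
#'   `diff_nucleosome`, `diff_methylation` plus the underlying `mut_*` /
#'   `wt_*` columns.
#' @export
diff_features <- function(partition, reference, end_model = NULL,
                          nucleosome_centers = NULL,
                          diff_methylation_gene_body = NA_real_) {
  mut <- fragment_summary(partition$mut, reference, end_model,
                          nucleosome_centers)
  wt <- fragment_summary(partition$wt, reference, end_model,
                         nucleosome_centers)
  tibble::tibble(
    diff_size = diff_metric(mut$frac_short, wt$frac_short),
    diff_ccca = diff_metric(mut$frac_ccca, wt$frac_ccca),
    diff_ctcc = diff_metric(mut$frac_ctcc, wt$frac_ctcc),
    diff_nucleosome = diff_metric(mut$frac_ends_in_nucleosome,
                                  wt$frac_ends_in_nucleosome),
    diff_methylation = diff_methylation_gene_body,
    mut_n = mut$n, wt_n = wt$n,
    mut_frac_short = mut$frac_short, wt_frac_short = wt$frac_short,
    mut_e_index = mut$e_index, wt_e_index = wt$e_index
  )
}
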
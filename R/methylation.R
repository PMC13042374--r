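# Context-stratified CpG methylation density for Mut- vs Wt-DNA on
# enzymatic methyl-sequencing style data. Methylation observations arrive
# as per-fragment (CpG position, state) pairs: state "M" (read as C,
# methylated) or "U" (read as T, unmethylated).

#' Build a promoter / gene-body / intergenic region classifier
#'
#' Promoters are TSS +/- `promoter_halfwidth` bp windows; gene bodies are
#' annotated gene spans minus the promoter windows; everything else is
#' intergenic. Precedence promoter > gene_body > intergenic makes the three
#' classes a disjoint partition of the genome.
#'
#' @param genes Gene annotation tibble (`chrom`, `tss`, `start`, `end`;
#'   0-based half-open span, 0-based TSS) — typically
#'   `reference$genes`.
#' @param promoter_halfwidth Promoter window half-width in bp (default 500).
#' @return A `region_classifier` object.
#' @export
region_classifier <- function(genes, promoter_halfwidth = 500) {
  genes <- tibble::as_tibble(genes)
  structure(list(genes = genes, promoter_halfwidth = promoter_halfwidth),
            class = "region_classifier")
}

#' Classify genomic positions into promoter / gene body / intergenic
#'
#' @param classifier A [region_classifier()].
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return Character vector in \{"promoter", "gene_body", "intergenic"\}.
#' @export
classify_region <- function(classifier, chrom, pos) {
  g <- classifier$genes
  hw <- classifier$promoter_halfwidth
  out <- rep("intergenic", length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    gg <- g[g$chrom == ch, , drop = FALSE]
    if (nrow(gg) == 0) next
    p <- pos[sel]
    in_prom <- in_intervals(p, gg$tss - hw, gg$tss + hw + 1L)
    in_gene <- in_intervals(p, gg$start, gg$end)
    out[sel][in_gene] <- "gene_body"
    out[sel][in_prom] <- "promoter"
  }
  out
}

# membership of positions in a union of half-open intervals [start, end)
in_intervals <- function(pos, starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  # merge overlapping intervals
  ms <- starts[1]; me <- ends[1]; k <- 1L
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me[k]) {
      me[k] <- max(me[k], ends[i])
    } else {
      k <- k + 1L; ms[k] <- starts[i]; me[k] <- ends[i]
    }
  }
  idx <- findInterval(pos, ms)
  idx > 0 & pos < me[pmax(idx, 1L)]
}

#' CpG positions covered by both Mut- and Wt-DNA
#'
#' Restricting both classes to this matched set compares methylation over
#' the same CpGs, removing coverage-composition effects. The match is
#' evaluated per sample (globally over all variant loci).
#'
#' @param partition An [partition_by_allele()] result.
#' @param meth_calls Tibble (`fragment_id`, `chrom`, `pos` (0-based CpG
#'   position), `state` in \{"M","U"\}).
#' @return Tibble (`chrom`, `pos`) of CpGs observed in at least one Mut and
#'   one Wt fragment.
#' @export
matched_cpgs <- function(partition, meth_calls) {
  meth_calls <- tibble::as_tibble(meth_calls)
  mut_cpg <- meth_calls %>%
    dplyr::semi_join(partition$mut, by = "fragment_id") %>%
    dplyr::distinct(.data$chrom, .data$pos)
  wt_cpg <- meth_calls %>%
    dplyr::semi_join(partition$wt, by = "fragment_id") %>%
    dplyr::distinct(.data$chrom, .data$pos)
  dplyr::inner_join(mut_cpg, wt_cpg, by = c("chrom", "pos"))
}

#' Region-stratified CpG methylation density
#'
#' Density = 100 * C / (C + T) where C counts methylated and T unmethylated
#' CpG observations (enzymatic conversion reads unmethylated C as T),
#' restricted to the supplied CpG set and stratified by region class. A
#' class with no observations is reported `NA` (undefined), never 0.
#'
#' @param fragments Fragment tibble selecting whose methylation calls count
#'   (e.g. `partition$mut`).
#' @param meth_calls Methylation-call tibble (see [matched_cpgs()]).
#' @param cpg_set Tibble (`chrom`, `pos`) of CpGs to include, typically
#'   from [matched_cpgs()]; `NULL` for all.
#' @param classifier A [region_classifier()].
#' @param reference Optional [reference_genome()]; when given, calls at
#'   positions that are not CpG in the reference raise an error (corrupt
#'   input guard).
#' @return Tibble (`region_class`, `n_meth`, `n_unmeth`, `density`) with one
#'   row per class.
#' @export
methylation_density <- function(fragments, meth_calls, cpg_set, classifier,
                                reference = NULL) {
  meth_calls <- tibble::as_tibble(meth_calls) %>%
    dplyr::semi_join(as_fragments(fragments), by = "fragment_id")
  if (!is.null(cpg_set)) {
    meth_calls <- dplyr::semi_join(meth_calls, tibble::as_tibble(cpg_set),
                                   by = c("chrom", "pos"))
  }
  if (!is.null(reference) && nrow(meth_calls) > 0) {
    dinuc <- ref_kmer(reference, meth_calls$chrom, meth_calls$pos, 2L)
    bad <- !is.na(dinuc) & dinuc != "CG"
    if (any(bad)) {
      i <- which(bad)[1]
      stop("methylation call at non-CpG reference position ",
           meth_calls$chrom[i], ":", meth_calls$pos[i])
    }
  }
  classes <- c("promoter", "gene_body", "intergenic")
  if (nrow(meth_calls) == 0) {
    return(tibble::tibble(region_class = classes, n_meth = 0L,
                          n_unmeth = 0L, density = NA_real_))
  }
  meth_calls$region_class <- classify_region(classifier, meth_calls$chrom,
                                             meth_calls$pos)
  tal <- meth_calls %>%
    dplyr::group_by(.data$region_class) %>%
    dplyr::summarise(
      n_meth = sum(.data$state == "M"),
      n_unmeth = sum(.data$state == "U"),
      .groups = "drop"
    )
  out <- tibble::tibble(region_class = classes) %>%
    dplyr::left_join(tal, by = "region_class") %>%
    dplyr::mutate(
      n_meth = dplyr::coalesce(.data$n_meth, 0L),
      n_unmeth = dplyr::coalesce(.data$n_unmeth, 0L),
      density = ifelse(.data$n_meth + .data$n_unmeth > 0,
                       100 * .data$n_meth / (.data$n_meth + .data$n_unmeth),
                       NA_real_)
    )
  out
}

#' Mut-minus-Wt methylation difference per region class
#'
#' @param mut_density,wt_density Density tibbles from
#'   [methylation_density()].
#' @return Tibble (`region_class`, `diff`); `NA` where either operand is
#'   undefined.
#' @export
diff_methylation <- function(mut_density, wt_density) {
  j <- dplyr::inner_join(mut_density, wt_density, by = "region_class",
                         suffix = c("_mut", "_wt"))
  tibble::tibble(
    region_class = j$region_class,
    diff = diff_metric(j$density_mut, j$density_wt)
  )
}

#' Full Mut-vs-Wt methylation contrast for one sample
#'
#' Computes matched CpGs, per-class densities for both halves of the
#' partition and their differences.
#'
#' @param partition An [partition_by_allele()] result.
#' @param meth_calls Methylation-call tibble.
#' @param classifier A [region_classifier()].
#' @param reference Optional [reference_genome()] for CpG validation.
#' @return List with `mut`, `wt` (density tibbles), `diff` (difference
#'   tibble) and `matched_cpgs`.
#' @export
methylation_contrast <- function(partition, meth_calls, classifier,
                                 reference = NULL) {
  cpgs <- matched_cpgs(partition, meth_calls)
  mut <- methylation_density(partition$mut, meth_calls, cpgs, classifier,
                             reference)
  wt <- methylation_density(partition$wt, meth_calls, cpgs, classifier,
                            reference)
  list(mut = mut, wt = wt, diff = diff_methylation(mut, wt),
       matched_cpgs = cpgs)
}
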
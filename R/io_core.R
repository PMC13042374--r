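#' @importFrom dplyr %>% filter mutate select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows n across all_of count
#'   distinct pull rename row_number slice first
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

# Fragment tables are tibbles with columns:
#   chrom, start (0-based inclusive), end (0-based exclusive),
#   fragment_id, mapq, strand, length, u_end, d_end
# u_end = start and d_end = end - 1 are both inclusive genomic positions of
# the upstream (lower-coordinate) and downstream (higher-coordinate) 5'/3'
# termini; single-position arithmetic (end models, nucleosome distances)
# operates on these.

#' Validate and complete a fragment table
#'
#' Checks coordinate invariants (0-based half-open, `start < end`) and fills
#' in the derived `length`, `u_end` and `d_end` columns.
#'
#' @param fragments A data frame with at least `chrom`, `start`, `end`.
#' @return A tibble with derived columns added.
#' @export
as_fragments <- function(fragments) {
  fragments <- as_tibble(fragments)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(fragments))
  if (length(missing_cols) > 0) {
    stop("fragment table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(fragments) > 0 && any(fragments$start >= fragments$end)) {
    bad <- which(fragments$start >= fragments$end)[1]
    stop("fragment ", bad, " has start >= end (coordinates must be 0-based half-open)")
  }
  if (!"fragment_id" %in% names(fragments)) {
    fragments$fragment_id <- sprintf("f%d", seq_len(nrow(fragments)))
  }
  if (!"mapq" %in% names(fragments)) fragments$mapq <- 60L
  if (!"strand" %in% names(fragments)) fragments$strand <- "+"
  fragments %>%
    mutate(
      length = .data$end - .data$start,
      u_end = .data$start,
      d_end = .data$end - 1L
    )
}

#' Read cfDNA fragments from a fragment BED or BAM file
#'
#' BED input is 6-column (chrom, start, end, name, mapq, strand), 0-based
#' half-open. BAM input collapses properly paired alignments to one fragment
#' per template, with the template length defining fragment size (requires
#' the Rsamtools package). Fragments with mapping quality below `min_mapq`
#' are dropped; alignments on chromosomes absent from `keep_chroms` (when
#' given) are skipped and counted in the `skipped_chrom` attribute.
#'
#' @param path Path to a fragment BED (optionally missing name/mapq/strand
#'   columns) or a BAM file.
#' @param min_mapq Minimum mapping quality to retain (default 60, the
#'   screening threshold used throughout the variant pipeline).
#' @param format `"auto"` (by extension), `"bed"` or `"bam"`.
#' @param keep_chroms Optional character vector of allowed chromosome names.
#' @return A fragment tibble (see [as_fragments()]).
#' @export
read_fragments <- function(path, min_mapq = 60, format = c("auto", "bed", "bam"),
                           keep_chroms = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  if (min_mapq < 0) stop("min_mapq must be >= 0")
  frags <- if (format == "bam") read_fragments_bam(path) else read_fragments_bed(path)
  n_skipped <- 0L
  if (!is.null(keep_chroms)) {
    keep <- frags$chrom %in% keep_chroms
    n_skipped <- sum(!keep)
    if (n_skipped > 0) {
      warning(n_skipped, " fragment(s) on unknown chromosomes skipped")
    }
    frags <- frags[keep, , drop = FALSE]
  }
  out <- as_fragments(frags) %>% filter(.data$mapq >= min_mapq)
  attr(out, "skipped_chrom") <- n_skipped
  out
}

read_fragments_bed <- function(path) {
  cols <- c("chrom", "start", "end", "fragment_id", "mapq", "strand")
  raw <- utils::read.table(path, sep = "", header = FALSE,
                           colClasses = "character",
                           col.names = cols[1:max(3, ncol_of_bed(path))],
                           fill = FALSE, stringsAsFactors = FALSE)
  raw <- as_tibble(raw)
  for (col in c("start", "end")) {
    val <- suppressWarnings(as.integer(raw[[col]]))
    if (anyNA(val)) {
      stop("malformed BED record at line ", which(is.na(val))[1], " of ", path)
    }
    raw[[col]] <- val
  }
  if ("mapq" %in% names(raw)) {
    raw$mapq <- suppressWarnings(as.integer(raw$mapq))
    if (anyNA(raw$mapq)) {
      stop("malformed mapq at line ", which(is.na(raw$mapq))[1], " of ", path)
    }
  }
  raw
}

ncol_of_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return(3L)
  length(strsplit(trimws(first), "[ \t]+")[[1]])
}

read_fragments_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM input requires the Rsamtools package")
  }
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isFirstMateRead = TRUE,
                                 isUnmappedQuery = FALSE,
                                 hasUnmappedMate = FALSE,
                                 isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "rname", "pos", "mpos", "isize", "mapq", "strand")
  )
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  tlen <- abs(b$isize)
  left <- pmin(b$pos, b$mpos)  # leftmost mate position (1-based)
  keep <- !is.na(tlen) & tlen > 0
  tibble(
    chrom = as.character(b$rname)[keep],
    start = as.integer(left[keep] - 1L),
    end = as.integer(left[keep] - 1L + tlen[keep]),
    fragment_id = b$qname[keep],
    mapq = as.integer(b$mapq)[keep],
    strand = as.character(b$strand)[keep]
  )
}

#' Write fragments as 6-column BED
#'
#' @param fragments Fragment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  fragments <- as_fragments(fragments)
  utils::write.table(
    fragments[, c("chrom", "start", "end", "fragment_id", "mapq", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Down-sample a deep fragment set
#'
#' Samples with more fragments than `threshold` are reduced to a uniform
#' random subset of exactly `target` fragments; shallower samples pass
#' through unchanged. Mirrors the convention of down-sampling cfDNA samples
#' deeper than 100 million reads to 60 million.
#'
#' @param fragments Fragment tibble.
#' @param threshold Count above which down-sampling triggers.
#' @param target Number of fragments to keep when triggered.
#' @param seed Integer seed making the subset reproducible.
#' @return A fragment tibble.
#' @export
downsample_fragments <- function(fragments, threshold = 100e6, target = 60e6,
                                 seed = 1L) {
  if (target > threshold) stop("target must be <= threshold")
  if (nrow(fragments) <= threshold) return(fragments)
  idx <- withr_seed(seed, sample.int(nrow(fragments), size = target))
  fragments[sort(idx), , drop = FALSE]
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Load a reference genome and gene annotation
#'
#' @param fasta_path FASTA file of chromosome sequences.
#' @param genes Optional gene annotation: a tibble or TSV path with columns
#'   `gene`, `chrom`, `tss`, `strand`, `start`, `end` (gene span, 0-based
#'   half-open; `tss` a 0-based position).
#' @return A `reference_genome` object: list with `seq` (a
#'   [Biostrings::DNAStringSet]) and `genes` (tibble, possibly empty).
#' @export
read_reference <- function(fasta_path, genes = NULL) {
  seq <- Biostrings::readDNAStringSet(fasta_path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  if (is.character(genes)) {
    genes <- readr::read_tsv(genes, show_col_types = FALSE)
  }
  reference_genome(seq, genes)
}

#' Construct a reference genome object
#'
#' @param seq Named [Biostrings::DNAStringSet] (or named character vector) of
#'   chromosome sequences.
#' @param genes Optional gene annotation tibble (`gene`, `chrom`, `tss`,
#'   `strand`, `start`, `end`).
#' @return A `reference_genome` object.
#' @export
reference_genome <- function(seq, genes = NULL) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(seq)
  if (is.null(names(seq)) || any(names(seq) == "")) {
    stop("reference sequences must be named by chromosome")
  }
  if (is.null(genes)) {
    genes <- tibble(gene = character(), chrom = character(), tss = integer(),
                    strand = character(), start = integer(), end = integer())
  }
  genes <- as_tibble(genes)
  if (nrow(genes) > 0) {
    lens <- setNames(Biostrings::width(seq), names(seq))
    if (any(genes$tss < 0 | genes$tss >= lens[genes$chrom])) {
      stop("gene annotation contains a TSS outside chromosome bounds")
    }
  }
  structure(list(seq = seq, genes = genes), class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("<reference_genome> ", length(x$seq), " chromosome(s), ",
      sum(Biostrings::width(x$seq)), " bp, ",
      nrow(x$genes), " gene(s)\n", sep = "")
  invisible(x)
}

#' Read a nucleosome-center track
#'
#' Accepts a BED of single-base center positions or of intervals whose
#' midpoints are used as centers.
#'
#' @param path BED path (chrom, start, end, ...).
#' @param dialect `"centers"` treats `start` as the 0-based center position;
#'   `"midpoints"` uses the interval midpoint.
#' @return Tibble with `chrom`, `center` (0-based position), sorted.
#' @export
read_nucleosome_track <- function(path, dialect = c("centers", "midpoints")) {
  dialect <- match.arg(dialect)
  bed <- utils::read.table(path, sep = "", header = FALSE,
                           stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  center <- if (dialect == "centers") bed$start else (bed$start + bed$end) %/% 2L
  tibble(chrom = bed$chrom, center = as.integer(center)) %>%
    arrange(.data$chrom, .data$center)
}

# derive a stream-specific 32-bit seed from a master seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483587L + 1L
}
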
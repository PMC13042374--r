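# 96-channel single-base-substitution (SBS96) machinery. The canonical
# channel order is substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then
# 5' flank (A,C,G,T), then 3' flank (A,C,G,T), with labels like "A[C>A]A".

SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide substitution contexts, in canonical order
#'
#' @return Character vector of length 96 (e.g. `"A[C>A]A"`).
#' @export
sbs96_contexts <- function() {
  ctx <- character(0)
  for (sub in SUBSTITUTIONS) {
    for (five in BASES) {
      for (three in BASES) {
        ctx <- c(ctx, paste0(five, "[", sub, "]", three))
      }
    }
  }
  ctx
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chr <- function(x) {
  n <- unique(nchar(x))
  if (length(x) == 0) return(character(0))
  if (length(n) == 1) {
    # fixed-width fast path: complement then reverse column-wise
    comp <- chartr("ACGT", "TGCA", x)
    out <- ""
    for (i in seq_len(n)) out <- paste0(substr(comp, i, i), out)
    return(out)
  }
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

#' Map calls to SBS96 context labels
#'
#' Applies the pyrimidine-strand convention: substitutions from a purine
#' reference (A or G) are reverse-complemented, together with their flanks,
#' so every channel has a C or T reference.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param five,three Single flanking reference bases (5' and 3' of the
#'   variant on the forward strand).
#' @return Character vector of context labels.
#' @export
sbs96_label <- function(ref, alt, five, three) {
  stopifnot(length(ref) == length(alt), length(five) == length(ref),
            length(three) == length(ref))
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, COMPLEMENT[ref], ref)
  a <- ifelse(flip, COMPLEMENT[alt], alt)
  f5 <- ifelse(flip, COMPLEMENT[three], five)
  f3 <- ifelse(flip, COMPLEMENT[five], three)
  paste0(f5, "[", r, ">", a, "]", f3)
}

#' Build a normalized 96-context mutation profile
#'
#' Bins each retained substitution into its trinucleotide context (pyrimidine
#' strand) and normalizes counts to frequencies. Calls whose flanking bases
#' contain N are skipped and counted in the `skipped_n` attribute.
#'
#' @param calls Tibble with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param reference A [reference_genome()].
#' @return Tibble with `context`, `count`, `frequency` (96 rows, canonical
#'   order; frequencies sum to 1 when any call survives).
#' @export
build_profile <- function(calls, reference) {
  calls <- tibble::as_tibble(calls)
  ctx <- sbs96_contexts()
  counts <- stats::setNames(integer(96), ctx)
  skipped <- 0L
  if (nrow(calls) > 0) {
    tri <- vapply(seq_len(nrow(calls)), function(i) {
      s <- reference$seq[[calls$chrom[i]]]
      p <- calls$pos[i]
      if (p < 2 || p > length(s) - 1) return(NA_character_)
      as.character(Biostrings::subseq(s, start = p - 1, width = 3))
    }, character(1))
    five <- substr(tri, 1, 1)
    three <- substr(tri, 3, 3)
    ok <- !is.na(tri) & !grepl("N", tri, fixed = TRUE)
    skipped <- sum(!ok)
    lab <- sbs96_label(calls$ref[ok], calls$alt[ok], five[ok], three[ok])
    tab <- table(factor(lab, levels = ctx))
    counts <- stats::setNames(as.integer(tab), ctx)
  }
  total <- sum(counts)
  out <- tibble::tibble(
    context = ctx,
    count = unname(counts),
    frequency = if (total > 0) unname(counts) / total else rep(0, 96)
  )
  attr(out, "skipped_n") <- skipped
  out
}

#' Select control mutation profiles as background signatures
#'
#' Draws `n_select` control samples (seeded, uniform, without replacement)
#' and returns their frequency vectors as background columns for the
#' deconvolution pool, modelling sequencing/experimental artifacts and
#' clonal hematopoiesis present in healthy cfDNA. Controls without any
#' variant are ineligible.
#'
#' @param control_profiles Named list of profile tibbles from
#'   [build_profile()].
#' @param n_select How many controls to use (0 allowed: no background).
#' @param seed Integer seed for the selection.
#' @return 96 x `n_select` numeric matrix with column names; zero columns
#'   when `n_select` is 0.
#' @export
build_background <- function(control_profiles, n_select, seed = 1L) {
  eligible <- Filter(function(p) sum(p$count) > 0, control_profiles)
  if (n_select > length(eligible)) {
    stop("n_select exceeds the number of eligible control profiles")
  }
  nm <- names(eligible)
  if (is.null(nm)) nm <- sprintf("control%d", seq_along(eligible))
  pick <- if (n_select == length(eligible)) seq_along(eligible) else {
    sort(withr_seed(seed, sample.int(length(eligible), n_select)))
  }
  mat <- vapply(eligible[pick], function(p) p$frequency, numeric(96))
  if (n_select == 0) {
    mat <- matrix(numeric(0), nrow = 96, ncol = 0)
  }
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 96)
  rownames(mat) <- sbs96_contexts()
  colnames(mat) <- nm[pick]
  mat
}

#' Assemble a signature pool for deconvolution
#'
#' @param signatures 96 x K nonnegative matrix with column names, each
#'   column summing to 1 (COSMIC-style SBS signatures and/or control
#'   backgrounds). A tibble with a `context` column is also accepted.
#' @param background Character vector (or logical of length K) naming the
#'   background columns; their summed contribution is excluded from the
#'   tumor-associated total.
#' @param artifact Character/logical flagging sequencing-artifact signatures;
#'   these are dropped before any fit.
#' @return A `signature_pool` object.
#' @export
signature_pool <- function(signatures, background = character(0),
                           artifact = character(0)) {
  if (is.data.frame(signatures)) {
    stopifnot("context" %in% names(signatures))
    m <- as.matrix(signatures[, setdiff(names(signatures), "context")])
    rownames(m) <- signatures$context
    signatures <- m
  }
  if (nrow(signatures) != 96) stop("signature matrix must have 96 rows")
  if (is.null(rownames(signatures))) rownames(signatures) <- sbs96_contexts()
  signatures <- signatures[sbs96_contexts(), , drop = FALSE]
  cs <- colSums(signatures)
  if (any(signatures < 0) || any(abs(cs - 1) > 1e-6)) {
    stop("signature columns must be nonnegative and sum to 1")
  }
  to_flag <- function(x) {
    if (is.logical(x)) x else colnames(signatures) %in% x
  }
  structure(list(
    matrix = signatures,
    is_background = to_flag(background),
    is_artifact = to_flag(artifact)
  ), class = "signature_pool")
}

#' @export
print.signature_pool <- function(x, ...) {
  cat("<signature_pool> ", ncol(x$matrix), " signatures (",
      sum(x$is_background), " background, ", sum(x$is_artifact),
      " artifact)\n", sep = "")
  invisible(x)
}

#' Read a COSMIC-layout signature matrix
#'
#' Expects a TSV whose first column holds the 96 context labels (any order)
#' and remaining columns one signature each.
#'
#' @param path TSV path.
#' @inheritParams signature_pool
#' @return A `signature_pool` object.
#' @export
read_signature_pool <- function(path, background = character(0),
                                artifact = character(0)) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  names(tab)[1] <- "context"
  signature_pool(tab, background = background, artifact = artifact)
}

# Lawson-Hanson active-set nonnegative least squares: min ||A x - b||, x >= 0
nnls_active_set <- function(A, b, tol = 1e-12, max_iter = 10 * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- qr.coef(qr(Ap), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) break
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
    }
    x <- z
    w <- crossprod(A, b - A %*% x)
  }
  pmax(as.numeric(x), 0)
}

#' Deconvolute a mutation profile against a signature pool
#'
#' Estimates the nonnegative mixing weights reproducing the sample's
#' 96-context frequency vector from the pool (COSMIC-style signatures plus
#' control-derived backgrounds). The fit runs seeded multiplicative updates
#' (the fixed-signature specialisation of NMF) to convergence, then polishes
#' with an exact active-set nonnegative least squares solve; weights are
#' reported as relative contributions summing to 1. The tumor-associated
#' total (`cosmic_total`) is the contribution mass on non-background
#' signatures.
#'
#' @param profile Profile tibble from [build_profile()], or a 96-vector of
#'   frequencies.
#' @param pool A [signature_pool()]; artifact-flagged columns are removed
#'   before fitting.
#' @param seed Seed for the multiplicative-update initialisation.
#' @param max_iter,tol Multiplicative-update stopping rule: stop when the
#'   relative change of reconstruction error falls below `tol` (default
#'   1e-8) or after `max_iter` (default 10000) iterations.
#' @return A `deconvolution` object with `contributions` (tibble:
#'   `signature`, `contribution`, `is_background`), `cosine` (similarity of
#'   input and reconstruction) and `cosmic_total`.
#' @export
deconvolute <- function(profile, pool, seed = 1L, max_iter = 10000,
                        tol = 1e-8) {
  b <- if (is.data.frame(profile)) profile$frequency else as.numeric(profile)
  stopifnot(length(b) == 96)
  if (sum(b) <= 0) stop("profile has no mutations to deconvolute")
  keep <- !pool$is_artifact
  A <- pool$matrix[, keep, drop = FALSE]
  is_bg <- pool$is_background[keep]

  # seeded multiplicative updates for min ||b - A x||^2, x >= 0
  x <- withr_seed(seed, stats::runif(ncol(A), 0.25, 0.75))
  AtB <- crossprod(A, b)
  AtA <- crossprod(A)
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    denom <- AtA %*% x
    x <- x * as.numeric(AtB) / pmax(as.numeric(denom), 1e-300)
    err <- sum((b - A %*% x)^2)
    if (is.finite(err_prev) && err_prev - err <= tol * max(err_prev, 1e-300)) break
    err_prev <- err
  }
  # exact polish
  x <- nnls_active_set(A, b)

  recon <- as.numeric(A %*% x)
  cosine <- if (sum(recon^2) == 0) 0 else {
    sum(b * recon) / sqrt(sum(b^2) * sum(recon^2))
  }
  total <- sum(x)
  contrib <- if (total > 0) x / total else x
  res <- structure(list(
    contributions = tibble::tibble(
      signature = colnames(A),
      contribution = as.numeric(contrib),
      is_background = is_bg
    ),
    cosine = cosine,
    cosmic_total = sum(contrib[!is_bg]),
    reconstruction = recon,
    input = b
  ), class = "deconvolution")
  res
}

#' @export
print.deconvolution <- function(x, ...) {
  cat("<deconvolution> cosine ", format(x$cosine, digits = 6),
      ", tumor-associated total ", format(x$cosmic_total, digits = 4),
      "\n", sep = "")
  top <- dplyr::arrange(x$contributions, dplyr::desc(.data$contribution))
  print(utils::head(top, 5))
  invisible(x)
}

#' @rdname deconvolute
#' @param x A `deconvolution` object.
#' @param ... Unused.
#' @export
tidy.deconvolution <- function(x, ...) {
  x$contributions
}

#' @rdname deconvolute
#' @export
glance.deconvolution <- function(x, ...) {
  tibble::tibble(
    cosine = x$cosine,
    cosmic_total = x$cosmic_total,
    n_signatures = nrow(x$contributions),
    n_background = sum(x$contributions$is_background)
  )
}
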
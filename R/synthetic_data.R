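# Seeded synthetic-cohort generator: toy genome, nucleosome track, control
# panel, and control/cancer samples with variants injected from a flat
# background profile and from chosen signature columns at a controlled
# mixing fraction. Fragment-level Mut effects (size shift, end-motif
# depletion, nucleosome-end enrichment, hypomethylation) are applied at the
# sampling stage conditional on the carried allele, so every downstream
# statistic is exercised honestly rather than being painted onto summaries.

#' Simulation configuration
#'
#' Defaults describe a desk-scale cohort: one 1-Mb chromosome at 42% GC
#' with 40 genes and nucleosomes every 200 bp; 10 controls and 10 cancers
#' with ~50 background variants per sample (rate 5e-5/bp) at allele
#' fraction 0.2 and locus depth ~30; cancer samples mix in tumor variants
#' drawn from three peaked signatures at `tumor_fraction` of their variant
#' load; healthy fragment lengths are a 90/10 mixture of mono- (166 +/- 10
#' bp) and di-nucleosomal (332 +/- 20 bp) components; tumor-derived
#' Mut fragments are shifted `mut_size_shift` bp, avoid CCCA/CTCC end
#' motifs (`mut_ccca_weight`, `mut_ctcc_weight` < 1), end preferentially
#' within +/- 50 bp of nucleosome centers (`mut_nucleosome_weight` > 1) and
#' are hypomethylated by `mut_methylation_shift` percentage points; bases
#' are misread at `error_rate`. Cohort fragments are anchored at variant
#' loci, mirroring the analysis step that extracts reads overlapping
#' somatic variants; `n_background_fragments` (default 0) adds unanchored
#' healthy fragments when nonzero.
#'
#' @param ... Overrides of the defaults listed above (see source for the
#'   full field list).
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    chrom_length = 1e6L,
    n_chroms = 1L,
    gc_content = 0.42,
    n_genes = 40L,
    gene_length = 8000L,
    nucleosome_spacing = 200L,
    nucleosome_jitter = 15L,
    nucleosome_window = 50L,
    n_controls = 10L,
    n_cancers = 10L,
    background_rate = 5e-5,
    tumor_fraction = 0.2,
    tumor_signatures = c(SYN1 = 0.5, SYN2 = 0.3, SYN3 = 0.2),
    variant_af = 0.2,
    depth_per_locus = 30,
    n_background_fragments = 0L,
    n_panel_fragments = 20000L,
    size_means = c(166, 332),
    size_sds = c(10, 20),
    size_weights = c(0.9, 0.1),
    min_length = 30L,
    error_rate = 1e-3,
    # healthy end-placement weights (apply to every fragment)
    nucleosome_weight = 2,
    # Mut-effect knobs, applied to fragments carrying tumor-origin alleles
    mut_size_shift = -20,
    mut_ccca_weight = 0.5,
    mut_ctcc_weight = 0.5,
    mut_nucleosome_weight = 1.5,
    mut_methylation_shift = -5,
    # baseline methylation density (%) per region class
    meth_promoter = 15,
    meth_gene_body = 80,
    meth_intergenic = 75
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(abs(sum(cfg$size_weights) - 1) < 1e-8,
            cfg$tumor_fraction >= 0, cfg$tumor_fraction <= 1,
            cfg$background_rate >= 0, cfg$background_rate <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a toy reference genome, gene annotation and nucleosome track
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; identical seeds give byte-identical
#'   output.
#' @return List with `reference` (a [reference_genome()]), `nucleosomes`
#'   (tibble `chrom`, `center`).
#' @export
simulate_reference <- function(config = sim_config(), seed = 1L) {
  if (config$chrom_length < 4 * config$nucleosome_spacing) {
    stop("genome too short for the configured nucleosome spacing")
  }
  withr_seed(derive_seed(seed, 11L), {
    gc <- config$gc_content
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chroms <- paste0("chr", seq_len(config$n_chroms))
    seqs <- vapply(chroms, function(ch) {
      paste(sample(BASES, config$chrom_length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    # non-overlapping gene spans on a regular grid with random offsets
    genes_per_chrom <- ceiling(config$n_genes / config$n_chroms)
    genes <- purrr::map_dfr(chroms, function(ch) {
      slots <- floor(config$chrom_length / (2 * config$gene_length))
      k <- min(genes_per_chrom, slots)
      slot_start <- (sample(slots, k) - 1L) * 2L * config$gene_length
      start <- slot_start + sample.int(config$gene_length %/% 2, k,
                                       replace = TRUE)
      tibble::tibble(
        gene = paste0(ch, "_g", seq_len(k)),
        chrom = ch,
        start = as.integer(start),
        end = as.integer(start + config$gene_length),
        strand = "+",
        tss = as.integer(start)
      )
    })
    nucleosomes <- purrr::map_dfr(chroms, function(ch) {
      centers <- seq(config$nucleosome_spacing %/% 2,
                     config$chrom_length - config$nucleosome_spacing,
                     by = config$nucleosome_spacing)
      jitter <- sample.int(2L * config$nucleosome_jitter + 1L,
                           length(centers), replace = TRUE) -
        config$nucleosome_jitter - 1L
      tibble::tibble(chrom = ch,
                     center = as.integer(sort(centers + jitter)))
    })
    list(
      reference = reference_genome(Biostrings::DNAStringSet(seqs), genes),
      nucleosomes = nucleosomes
    )
  })
}

# ---- precomputed per-chromosome placement index ---------------------------

collapse_trinuc <- function(tri) {
  center <- substr(tri, 2, 2)
  flip <- center %in% c("A", "G")
  out <- tri
  out[flip] <- revcomp_chr(tri[flip])
  list(context = out, flipped = flip)
}

# positions-by-context, motif flags, nucleosome proximity and CpG sites
build_sim_index <- function(reference, nucleosomes, window = 50) {
  idx <- list()
  for (ch in names(reference$seq)) {
    s <- reference$seq[[ch]]
    len <- length(s)
    flag_at <- function(pattern, offset) {
      v <- logical(len)
      st <- Biostrings::start(Biostrings::matchPattern(pattern, s))
      p <- st - 1L + offset  # 0-based flagged position
      p <- p[p >= 0 & p < len]
      v[p + 1L] <- TRUE
      v
    }
    near <- logical(len)
    cc <- nucleosomes$center[nucleosomes$chrom == ch]
    for (c0 in cc) {
      lo <- max(c0 - window, 0L); hi <- min(c0 + window, len - 1L)
      near[(lo + 1L):(hi + 1L)] <- TRUE
    }
    # trinucleotide context classes (1-based interior positions)
    chars <- strsplit(as.character(s), "")[[1]]
    i <- 2:(len - 1L)
    tri <- paste0(chars[i - 1L], chars[i], chars[i + 1L])
    coll <- collapse_trinuc(tri)
    ctx_positions <- split(i, coll$context)
    ctx_flipped <- split(coll$flipped, coll$context)
    cpg_start <- Biostrings::start(Biostrings::matchPattern("CG", s)) - 1L
    idx[[ch]] <- list(
      len = len,
      u_ccca = flag_at("CCCA", 0L),
      d_ccca = flag_at("TGGG", 3L),
      u_ctcc = flag_at("CTCC", 2L),
      d_ctcc = flag_at("GGAG", 1L),
      near_nuc = near,
      ctx_positions = ctx_positions,
      ctx_flipped = ctx_flipped,
      cpg = cpg_start  # 0-based positions of CpG "C"
    )
  }
  idx
}

# attach per-CpG region classes so per-fragment methylation draws need no
# interval lookups
add_cpg_classes <- function(index, classifier) {
  for (ch in names(index)) {
    index[[ch]]$cpg_class <- classify_region(
      classifier, rep(ch, length(index[[ch]]$cpg)), index[[ch]]$cpg)
  }
  index
}

# draw fragment lengths from the configured mixture, optionally shifted
draw_lengths <- function(n, config, shift = 0) {
  comp <- sample.int(length(config$size_weights), n, replace = TRUE,
                     prob = config$size_weights)
  L <- round(stats::rnorm(n, config$size_means[comp] + shift,
                          config$size_sds[comp]))
  pmax(as.integer(L), config$min_length)
}

# place one fragment of length L covering 0-based locus p0 on chrom index
# `ci`, end-position preferences encoded as multiplicative weights
place_fragment <- function(ci, p0, L, w_nuc, w_ccca, w_ctcc) {
  lo <- max(p0 - L + 1L, 0L)
  hi <- min(p0, ci$len - L)
  if (hi < lo) return(max(0L, min(p0, ci$len - L)))
  u <- lo:hi
  d <- u + L - 1L
  w <- w_nuc^(ci$near_nuc[u + 1L] + ci$near_nuc[d + 1L]) *
    w_ccca^(ci$u_ccca[u + 1L] + ci$d_ccca[d + 1L]) *
    w_ctcc^(ci$u_ctcc[u + 1L] + ci$d_ctcc[d + 1L])
  if (all(w == 0)) w <- rep(1, length(u))
  u[sample.int(length(u), 1L, prob = w)]
}

# sample a variant position for each requested 96-channel; returns tibble
sample_variant_sites <- function(channels, reference, index, min_gap = 2L) {
  ctx_all <- sbs96_contexts()
  chroms <- names(reference$seq)
  out <- vector("list", length(channels))
  used <- new.env(parent = emptyenv())
  for (k in seq_along(channels)) {
    lab <- ctx_all[channels[k]]
    # "F[R>A]T" -> collapsed trinucleotide FRT and alt base
    five <- substr(lab, 1, 1); r <- substr(lab, 3, 3)
    alt_pyr <- substr(lab, 5, 5); three <- substr(lab, 7, 7)
    tri <- paste0(five, r, three)
    for (attempt in 1:50) {
      ch <- sample(chroms, 1L)
      pos_list <- index[[ch]]$ctx_positions[[tri]]
      if (is.null(pos_list) || length(pos_list) == 0) next
      j <- sample.int(length(pos_list), 1L)
      pos <- pos_list[j]           # 1-based
      flipped <- index[[ch]]$ctx_flipped[[tri]][j]
      key_ok <- TRUE
      for (g in (-min_gap):min_gap) {
        if (!is.null(used[[paste(ch, pos + g)]])) { key_ok <- FALSE; break }
      }
      if (!key_ok) next
      used[[paste(ch, pos)]] <- TRUE
      ref_base <- if (flipped) unname(COMPLEMENT[r]) else r
      alt_base <- if (flipped) unname(COMPLEMENT[alt_pyr]) else alt_pyr
      out[[k]] <- tibble::tibble(chrom = ch, pos = pos, ref = ref_base,
                                 alt = alt_base, channel = lab)
      break
    }
  }
  dplyr::bind_rows(out)
}

region_meth_level <- function(config, region_class) {
  c(promoter = config$meth_promoter, gene_body = config$meth_gene_body,
    intergenic = config$meth_intergenic)[region_class]
}

simulate_sample <- function(sample_id, label, config, reference, index,
                            pool_matrix, seed) {
  withr_seed(seed, {
    genome_len <- sum(vapply(index, function(x) x$len, numeric(1)))
    n_bg <- stats::rpois(1, config$background_rate * genome_len)
    n_bg <- max(n_bg, 5L)
    bg_channels <- sample.int(96, n_bg, replace = TRUE)
    f <- if (label == "cancer") config$tumor_fraction else 0
    n_tu <- if (f > 0) round(n_bg * f / (1 - f)) else 0L
    tu_channels <- integer(0)
    if (n_tu > 0) {
      w <- config$tumor_signatures
      mix <- as.numeric(pool_matrix[, names(w), drop = FALSE] %*% w)
      tu_channels <- sample.int(96, n_tu, replace = TRUE, prob = mix)
    }
    sites <- sample_variant_sites(c(bg_channels, tu_channels), reference,
                                  index)
    sites$origin <- rep(c("background", "tumor"),
                        c(n_bg, n_tu))[seq_len(nrow(sites))]

    depths <- pmax(stats::rpois(nrow(sites), config$depth_per_locus), 2L)
    n_frag <- sum(depths)
    fr_chrom <- character(n_frag); fr_start <- integer(n_frag)
    fr_len <- integer(n_frag)
    bc_base <- character(n_frag); bc_pos <- integer(n_frag)
    tr_locus <- character(n_frag); tr_origin <- character(n_frag)
    tr_carrier <- logical(n_frag); tr_effect <- logical(n_frag)
    mc_pos <- vector("list", n_frag)
    mc_state <- vector("list", n_frag)
    meth_lv <- c(promoter = config$meth_promoter,
                 gene_body = config$meth_gene_body,
                 intergenic = config$meth_intergenic)
    fid <- 0L
    for (v in seq_len(nrow(sites))) {
      ch <- sites$chrom[v]
      ci <- index[[ch]]
      p0 <- sites$pos[v] - 1L  # 0-based
      depth <- depths[v]
      carrier <- stats::rbinom(depth, 1, config$variant_af) == 1
      effect <- carrier & sites$origin[v] == "tumor"
      Ls <- integer(depth)
      Ls[!effect] <- draw_lengths(sum(!effect), config, 0)
      Ls[effect] <- draw_lengths(sum(effect), config, config$mut_size_shift)
      err_flip <- stats::runif(depth) < config$error_rate
      for (i in seq_len(depth)) {
        fid <- fid + 1L
        u0 <- if (effect[i]) {
          place_fragment(ci, p0, Ls[i],
                         config$nucleosome_weight *
                           config$mut_nucleosome_weight,
                         config$mut_ccca_weight, config$mut_ctcc_weight)
        } else {
          place_fragment(ci, p0, Ls[i], config$nucleosome_weight, 1, 1)
        }
        d0 <- u0 + Ls[i] - 1L
        fr_chrom[fid] <- ch; fr_start[fid] <- u0; fr_len[fid] <- Ls[i]
        truth_base <- if (carrier[i]) sites$alt[v] else sites$ref[v]
        bc_base[fid] <- if (err_flip[i]) {
          sample(setdiff(BASES, truth_base), 1L)
        } else truth_base
        bc_pos[fid] <- sites$pos[v]
        # per-fragment CpG methylation states (region classes precomputed;
        # cpg positions are sorted, so locate the covered run by bisection)
        k_lo <- findInterval(u0 - 1L, ci$cpg) + 1L
        k_hi <- findInterval(d0 - 1L, ci$cpg)
        ki <- if (k_hi >= k_lo) k_lo:k_hi else integer(0)
        if (length(ki) > 0) {
          lvl <- unname(meth_lv[ci$cpg_class[ki]])
          if (effect[i]) lvl <- pmax(lvl + config$mut_methylation_shift, 0)
          mc_pos[[fid]] <- ci$cpg[ki]
          mc_state[[fid]] <- ifelse(stats::runif(length(ki)) < lvl / 100,
                                    "M", "U")
        }
        tr_locus[fid] <- paste0(ch, ":", sites$pos[v])
        tr_origin[fid] <- sites$origin[v]
        tr_carrier[fid] <- carrier[i]; tr_effect[fid] <- effect[i]
      }
    }
    ids <- sprintf("%s_f%06d", sample_id, seq_len(n_frag))
    frag_rows <- list(tibble::tibble(
      chrom = fr_chrom, start = fr_start, end = fr_start + fr_len,
      fragment_id = ids, mapq = 60L, strand = "+"
    ))
    call_rows <- list(tibble::tibble(
      fragment_id = ids, chrom = fr_chrom, pos = bc_pos, base = bc_base,
      qual = 40L
    ))
    n_meth <- lengths(mc_pos)
    meth_rows <- list(tibble::tibble(
      fragment_id = rep(ids, n_meth),
      chrom = rep(fr_chrom, n_meth),
      pos = as.integer(unlist(mc_pos, use.names = FALSE)),
      state = as.character(unlist(mc_state, use.names = FALSE))
    ))
    frag_truth <- list(tibble::tibble(
      fragment_id = ids, locus = tr_locus, origin = tr_origin,
      carrier = tr_carrier, effect = tr_effect
    ))

    # background fragments not tied to variant loci (healthy placement,
    # upstream-end weighted)
    n_free <- config$n_background_fragments
    free <- NULL
    if (n_free > 0) {
      chroms <- names(index)
      lens <- vapply(index, function(x) x$len, numeric(1))
      chs <- sample(chroms, n_free, replace = TRUE, prob = lens)
      Ls <- draw_lengths(n_free, config, 0)
      u0 <- integer(n_free)
      for (ch in unique(chs)) {
        sel <- chs == ch
        ci <- index[[ch]]
        w <- config$nucleosome_weight^ci$near_nuc
        cand_max <- ci$len - max(Ls[sel])
        u0[sel] <- sample.int(cand_max, sum(sel), replace = TRUE,
                              prob = w[seq_len(cand_max)]) - 1L
      }
      free <- tibble::tibble(
        chrom = chs, start = u0, end = u0 + Ls,
        fragment_id = sprintf("%s_b%06d", sample_id, seq_len(n_free)),
        mapq = 60L, strand = "+"
      )
    }

    fragments <- dplyr::bind_rows(c(frag_rows, list(free)))
    base_calls <- dplyr::bind_rows(call_rows)

    # stray sequencing-error base calls away from variant loci
    n_err <- stats::rpois(1, sum(fragments$end - fragments$start) *
                            config$error_rate)
    err <- NULL
    if (n_err > 0) {
      pick <- sample.int(nrow(fragments), n_err, replace = TRUE,
                         prob = fragments$end - fragments$start)
      off <- floor(stats::runif(n_err) *
                     (fragments$end[pick] - fragments$start[pick]))
      pos1 <- fragments$start[pick] + as.integer(off) + 1L
      err_ch <- fragments$chrom[pick]
      refb <- character(n_err)
      for (ch in unique(err_ch)) {
        sel <- err_ch == ch
        s <- as.character(reference$seq[[ch]])
        refb[sel] <- substring(s, pos1[sel], pos1[sel])
      }
      altb <- vapply(refb, function(r) sample(setdiff(BASES, r), 1L),
                     character(1))
      err <- tibble::tibble(
        fragment_id = fragments$fragment_id[pick],
        chrom = fragments$chrom[pick], pos = pos1, base = altb, qual = 40L
      )
      base_calls <- dplyr::bind_rows(base_calls, err)
    }

    list(
      fragments = fragments,
      base_calls = base_calls,
      meth_calls = dplyr::bind_rows(meth_rows),
      label = label,
      truth = list(
        variants = sites,
        fragments = dplyr::bind_rows(frag_truth),
        errors = if (is.null(err)) tibble::tibble(
          fragment_id = character(), chrom = character(), pos = integer(),
          base = character(), qual = integer()
        ) else err
      )
    )
  })
}

#' Simulate a full cohort with ground truth
#'
#' Control samples draw variants from a flat background profile plus
#' sequencing-error artifacts; cancer samples additionally draw
#' tumor-origin variants from the configured signature mixture so that they
#' make up `tumor_fraction` of the variant load. Fragments covering
#' tumor-variant alleles are sampled with the configured Mut-effect shifts.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()] (list with `reference`
#'   and `nucleosomes`).
#' @param pool A [signature_pool()] providing the tumor signature columns
#'   named in `config$tumor_signatures`.
#' @param seed Integer master seed.
#' @param index Optional precomputed placement index (from a previous call,
#'   exposed through the `sim_index` attribute of the result) to avoid
#'   re-indexing the same reference.
#' @return A `sim_cohort`: list with `samples` (named list; each has
#'   `fragments`, `base_calls`, `meth_calls`, `label`, `truth`), `labels`
#'   tibble, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), reference, pool,
                            seed = 1L, index = NULL) {
  missing_sigs <- setdiff(names(config$tumor_signatures),
                          colnames(pool$matrix))
  if (length(missing_sigs) > 0 && config$tumor_fraction > 0 &&
      config$n_cancers > 0) {
    stop("tumor signature(s) absent from pool: ",
         paste(missing_sigs, collapse = ", "))
  }
  if (is.null(index)) {
    index <- build_sim_index(reference$reference, reference$nucleosomes,
                             config$nucleosome_window)
    index <- add_cpg_classes(index,
                             region_classifier(reference$reference$genes))
  }
  ids <- c(sprintf("control_%02d", seq_len(config$n_controls)),
           sprintf("cancer_%02d", seq_len(config$n_cancers)))
  labels <- rep(c("control", "cancer"),
                c(config$n_controls, config$n_cancers))
  samples <- purrr::map2(ids, seq_along(ids), function(id, k) {
    simulate_sample(id, labels[k], config, reference$reference, index,
                    pool$matrix, derive_seed(seed, 100L + k))
  })
  names(samples) <- ids
  out <- structure(list(
    samples = samples,
    labels = tibble::tibble(sample_id = ids, label = labels),
    config = config
  ), class = "sim_cohort")
  attr(out, "sim_index") <- index
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", sum(x$labels$label == "control"), " controls + ",
      sum(x$labels$label == "cancer"), " cancers\n", sep = "")
  invisible(x)
}

#' Simulate a healthy-control panel for the end model
#'
#' Control-like fragments drawn from a seed stream disjoint from the cohort
#' samples; feed the result to [build_end_model()].
#'
#' @inheritParams simulate_cohort
#' @return Fragment tibble of `config$n_panel_fragments` rows.
#' @export
simulate_panel <- function(config = sim_config(), reference, seed = 1L,
                           index = NULL) {
  if (is.null(index)) {
    index <- build_sim_index(reference$reference, reference$nucleosomes,
                             config$nucleosome_window)
  }
  withr_seed(derive_seed(seed, 999983L), {
    n <- config$n_panel_fragments
    chroms <- names(index)
    lens <- vapply(index, function(x) x$len, numeric(1))
    chs <- sample(chroms, n, replace = TRUE, prob = lens)
    Ls <- draw_lengths(n, config, 0)
    u0 <- integer(n)
    for (ch in unique(chs)) {
      sel <- chs == ch
      ci <- index[[ch]]
      w <- config$nucleosome_weight^ci$near_nuc
      cand_max <- ci$len - max(Ls[sel])
      u0[sel] <- sample.int(cand_max, sum(sel), replace = TRUE,
                            prob = w[seq_len(cand_max)]) - 1L
    }
    tibble::tibble(
      chrom = chs, start = u0, end = u0 + Ls,
      fragment_id = sprintf("panel_f%06d", seq_len(n)),
      mapq = 60L, strand = "+"
    )
  })
}

#' Analytically expected Diff-size and Diff-methylation under a config
#'
#' Among Mut-DNA fragments a fraction `tumor_fraction` carry tumor-origin
#' alleles and feel the configured effects; Wt-DNA fragments never do.
#' Expected Diff-size is therefore `tumor_fraction *
#' (F_shifted(150.5) - F_healthy(150.5))` with `F` the mixture CDF of
#' rounded fragment lengths. For Diff-methylation the effect fragments'
#' share of CpG observations is length-weighted (shorter effect fragments
#' cover fewer CpGs), so the expected gene-body difference is
#' `w * mut_methylation_shift` with
#' `w = f*Lm / (f*Lm + (1-f)*Lw)`, `Lm`/`Lw` the mean shifted/healthy
#' fragment lengths.
#'
#' @param config A [sim_config()].
#' @return One-row tibble (`diff_size`, `diff_methylation`).
#' @export
expected_diffs <- function(config) {
  mix_cdf <- function(x, shift) {
    sum(config$size_weights *
          stats::pnorm(x, config$size_means + shift, config$size_sds))
  }
  f <- config$tumor_fraction
  l_wt <- sum(config$size_weights * config$size_means)
  l_mut <- l_wt + config$mut_size_shift
  w_cpg <- if (f > 0) f * l_mut / (f * l_mut + (1 - f) * l_wt) else 0
  tibble::tibble(
    diff_size = f * (mix_cdf(150.5, config$mut_size_shift) -
                       mix_cdf(150.5, 0)),
    diff_methylation = w_cpg * config$mut_methylation_shift
  )
}
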
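# End-to-end per-sample pipeline: pileup -> candidate calls -> filter
# cascade -> mutation profile + allele partition -> fragmentomic and
# methylation contrasts -> classifier features.

#' Path to the shipped synthetic signature pool
#'
#' A small synthetic stand-in for a COSMIC-style SBS matrix: eight sharply
#' peaked signature columns (SYN1-SYN8) plus two smooth background-like
#' columns (BG1, BG2). Real COSMIC matrices in the same TSV layout are
#' drop-in replacements via [read_signature_pool()].
#'
#' @return File path of the TSV.
#' @export
synthetic_pool_path <- function() {
  system.file("extdata", "synthetic_sbs_pool.tsv", package = "freesv",
              mustWork = TRUE)
}

#' Load the shipped synthetic signature pool
#'
#' @param background Columns to flag as background (default the shipped
#'   BG1/BG2).
#' @param artifact Columns to flag as sequencing artifacts (dropped before
#'   fitting).
#' @return A [signature_pool()].
#' @export
load_synthetic_pool <- function(background = c("BG1", "BG2"),
                                artifact = character(0)) {
  read_signature_pool(synthetic_pool_path(), background = background,
                      artifact = artifact)
}

#' Run the variant screen on one sample
#'
#' Builds the pileup at every locus with a non-reference observation, calls
#' candidates, and applies the filter cascade.
#'
#' @param sample One cohort sample (list with `fragments`, `base_calls`).
#' @param reference A [reference_genome()].
#' @param resources A [filter_resources()].
#' @param mode `"wgs"` or `"emseq"`.
#' @param error_rate Per-base error rate for the detection-quality score.
#' @return List with `calls` (all candidates with filter flags) and
#'   `retained` (passing calls).
#' @export
screen_sample <- function(sample, reference,
                          resources = filter_resources(autosomes = NULL),
                          mode = "wgs", error_rate = 1e-3) {
  if (is.null(resources$autosomes)) {
    resources$autosomes <- names(reference$seq)
  }
  pile <- pileup_from_fragments(sample$fragments, sample$base_calls,
                                reference)
  cands <- call_candidates(pile, mode = mode, error_rate = error_rate)
  calls <- apply_filter_cascade(cands, resources)
  list(calls = calls, retained = retained_calls(calls))
}

#' Compute the full feature row for one sample
#'
#' Runs the variant screen, builds the 96-context profile from retained
#' calls, partitions fragments by allele, and computes the five Diff-*
#' contrasts.
#'
#' @inheritParams screen_sample
#' @param end_model An [build_end_model()] result.
#' @param nucleosome_centers Tibble (`chrom`, `center`).
#' @param classifier A [region_classifier()].
#' @return List with `profile`, `diffs` (one-row tibble), `retained`,
#'   `partition`.
#' @export
sample_features <- function(sample, reference, end_model,
                            nucleosome_centers, classifier,
                            resources = filter_resources(autosomes = NULL),
                            mode = "wgs", error_rate = 1e-3) {
  scr <- screen_sample(sample, reference, resources, mode, error_rate)
  profile <- build_profile(scr$retained, reference)
  part <- partition_by_allele(sample$fragments, sample$base_calls,
                              scr$retained)
  meth <- if (!is.null(sample$meth_calls) && nrow(sample$meth_calls) > 0) {
    methylation_contrast(part, sample$meth_calls, classifier)
  } else NULL
  dm <- if (is.null(meth)) NA_real_ else {
    meth$diff$diff[meth$diff$region_class == "gene_body"]
  }
  diffs <- diff_features(part, reference, end_model, nucleosome_centers,
                         diff_methylation_gene_body = dm)
  list(profile = profile, diffs = diffs, retained = scr$retained,
       partition = part, methylation = meth)
}

#' Assemble the classifier feature matrix for a whole cohort
#'
#' Maps [sample_features()] over every sample of a simulated (or otherwise
#' assembled) cohort and binds the rows into the labelled feature tibble
#' that [nested_cv()] consumes.
#'
#' @param cohort A [simulate_cohort()] result (or any list with `samples`
#'   and `labels` of the same shape).
#' @inheritParams sample_features
#' @param mode `"freesv"` or `"freesv_plus"`.
#' @param genomewide Optional genome-wide feature table for
#'   `"freesv_plus"`.
#' @return Feature tibble (see [assemble_features()]).
#' @export
cohort_features <- function(cohort, reference, end_model,
                            nucleosome_centers, classifier,
                            resources = filter_resources(autosomes = NULL),
                            mode = "freesv", genomewide = NULL,
                            error_rate = 1e-3) {
  per_sample <- purrr::map(cohort$samples, sample_features,
                           reference = reference, end_model = end_model,
                           nucleosome_centers = nucleosome_centers,
                           classifier = classifier, resources = resources,
                           error_rate = error_rate)
  profiles <- purrr::map(per_sample, "profile")
  diffs <- purrr::imap_dfr(per_sample, function(s, id) {
    dplyr::mutate(s$diffs, sample_id = id)
  })
  assemble_features(profiles, diffs, mode = mode, genomewide = genomewide,
                    labels = cohort$labels)
}

#' Per-sample mutation profiles and deconvolutions for a cohort
#'
#' Screens every sample, builds its profile and deconvolutes it against
#' `pool` augmented with background columns drawn from the cohort's control
#' profiles.
#'
#' @inheritParams cohort_features
#' @param pool A [signature_pool()] of COSMIC-style columns.
#' @param n_background Number of control profiles to add as background
#'   signatures (capped at the number of eligible controls).
#' @param seed Seed for background selection and deconvolution starts.
#' @return Tibble (`sample_id`, `label`, `n_variants`, `cosine`,
#'   `cosmic_total`).
#' @export
cohort_deconvolution <- function(cohort, reference, pool,
                                 n_background = 10, seed = 1L,
                                 resources = filter_resources(autosomes = NULL),
                                 error_rate = 1e-3) {
  screens <- purrr::map(cohort$samples, screen_sample, reference = reference,
                        resources = resources, error_rate = error_rate)
  profiles <- purrr::map(screens, function(s) build_profile(s$retained,
                                                            reference))
  ctrl_ids <- cohort$labels$sample_id[cohort$labels$label == "control"]
  bg <- build_background(profiles[ctrl_ids],
                         min(n_background, length(ctrl_ids)), seed)
  aug <- signature_pool(
    cbind(pool$matrix, bg),
    background = c(colnames(pool$matrix)[pool$is_background], colnames(bg)),
    artifact = colnames(pool$matrix)[pool$is_artifact]
  )
  purrr::imap_dfr(profiles, function(p, id) {
    if (sum(p$count) == 0) {
      return(tibble::tibble(sample_id = id, n_variants = 0L,
                            cosine = NA_real_, cosmic_total = NA_real_))
    }
    d <- deconvolute(p, aug, seed = seed)
    tibble::tibble(sample_id = id, n_variants = sum(p$count),
                   cosine = d$cosine, cosmic_total = d$cosmic_total)
  }) %>%
    dplyr::left_join(cohort$labels, by = "sample_id") %>%
    dplyr::select("sample_id", "label", dplyr::everything())
}
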
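# Mutation-centred analysis: wild-type/mutant peptide pairs reporting on the
# same mutation site are collapsed per (bait, mutation) into paired count
# observations. Two metrics summarise each domain-mutation pair: the
# mutation enrichment score
#   sum_i nc_mut_i / (nc_wt_i + nc_mut_i) - sum_i nc_wt_i / (nc_wt_i + nc_mut_i)
# bounded by the number of observations n, and the two-sided Mann-Whitney
# p value comparing the wild-type against the mutant count vectors. A
# positive score indicates a mutation enhancing binding, a negative score a
# mutation diminishing binding.

#' Collapse peptide pairs into per-mutation paired observations
#'
#' Every designed wild-type/mutant pair contributes one observation per
#' replicate in which at least one member was observed: the merged
#' normalised counts (`nc_wt`, `nc_mut`), with an absent member counted as
#' zero. Observations where both counts are zero are dropped, since the
#' count fractions are undefined there.
#'
#' @param merged merged count tibble from [normalise_and_merge()].
#' @param design design tibble from [design_library()].
#' @return tibble `bait_id`, `protein_id`, `mutation`, `window_start`,
#'   `replicate`, `nc_wt`, `nc_mut`.
#' @export
collapse_pairs <- function(merged, design) {
  designed <- unique(c(design$wt_peptide, design$mut_peptide))
  stray <- setdiff(unique(merged$peptide), designed)
  if (length(stray) > 0) {
    warn(sprintf(
      "%d peptide(s) without a designed partner excluded", length(stray)
    ))
  }
  lookup <- merged %>%
    dplyr::select("bait_id", "peptide", "replicate", "merged_count")
  pairs <- design %>%
    dplyr::distinct(
      .data$protein_id, .data$mutation, .data$window_start,
      .data$wt_peptide, .data$mut_peptide
    )
  reps <- merged %>% dplyr::distinct(.data$bait_id, .data$replicate)
  tidyr::crossing(reps, pairs) %>%
    dplyr::left_join(
      dplyr::rename(lookup, wt_peptide = "peptide", nc_wt = "merged_count"),
      by = c("bait_id", "replicate", "wt_peptide")
    ) %>%
    dplyr::left_join(
      dplyr::rename(lookup, mut_peptide = "peptide", nc_mut = "merged_count"),
      by = c("bait_id", "replicate", "mut_peptide")
    ) %>%
    dplyr::mutate(
      nc_wt = dplyr::coalesce(.data$nc_wt, 0),
      nc_mut = dplyr::coalesce(.data$nc_mut, 0)
    ) %>%
    dplyr::filter(.data$nc_wt > 0 | .data$nc_mut > 0) %>%
    dplyr::select(
      "bait_id", "protein_id", "mutation", "window_start", "replicate",
      "nc_wt", "nc_mut"
    )
}

#' Mutation enrichment score
#'
#' Exact evaluation of the paired count-fraction difference; the result is
#' bounded by the number of observations (`score` in \eqn{[-n, +n]}), and
#' reaches \eqn{\pm n} only when every observation is fully one-sided.
#'
#' @param nc_wt,nc_mut numeric vectors of paired normalised counts; no
#'   observation may have both entries zero.
#' @return the enrichment score (positive: mutation enhances binding).
#' @export
enrichment_score <- function(nc_wt, nc_mut) {
  stopifnot(length(nc_wt) == length(nc_mut))
  if (length(nc_wt) == 0) {
    abort("Enrichment score undefined for zero observations")
  }
  if (any(nc_wt < 0 | nc_mut < 0)) abort("Counts must be non-negative")
  tot <- nc_wt + nc_mut
  if (any(tot == 0)) {
    abort("Observations with nc_wt = nc_mut = 0 must be excluded first")
  }
  sum(nc_mut / tot) - sum(nc_wt / tot)
}

#' Two-sided Mann-Whitney test on paired count vectors
#'
#' Compares the vector of wild-type counts against the vector of mutant
#' counts across all observations of a domain-mutation pair. The exact null
#' distribution is used when the pooled sample size is at most 20 and there
#' are no ties; otherwise midranks with the tie-corrected normal
#' approximation. Degenerate input (all pooled values identical) returns
#' p = 1.
#'
#' @param nc_wt,nc_mut numeric count vectors (need not be the same length
#'   when called on unpaired data).
#' @return the two-sided p value.
#' @export
mw_test <- function(nc_wt, nc_mut) {
  stopifnot(length(nc_wt) >= 1, length(nc_mut) >= 1)
  pooled <- c(nc_wt, nc_mut)
  if (length(unique(pooled)) == 1) return(1)
  ties <- anyDuplicated(pooled) > 0
  use_exact <- !ties && length(pooled) <= 20
  res <- suppressWarnings(
    wilcox.test(nc_wt, nc_mut, exact = use_exact, correct = TRUE)
  )
  unname(res$p.value)
}

#' Classify the direction of a mutation effect
#'
#' @param score mutation enrichment score(s).
#' @param p_value Mann-Whitney p value(s).
#' @param p_cutoff significance cut-off (the screen's primary cut-off is
#'   0.001; 0.01 is the relaxed setting).
#' @return factor: `enhancing` (significant, score > 0), `diminishing`
#'   (significant, score < 0), otherwise `neutral`.
#' @export
classify_direction <- function(score, p_value, p_cutoff = 0.001) {
  out <- ifelse(
    p_value <= p_cutoff & score > 0, "enhancing",
    ifelse(p_value <= p_cutoff & score < 0, "diminishing", "neutral")
  )
  factor(out, levels = c("diminishing", "neutral", "enhancing"))
}

#' Count windows with individually significant wild-type/mutant differences
#'
#' Per peptide window, a Mann-Whitney test on that window's replicate-level
#' wild-type versus mutant counts; windows with fewer than two replicates
#' are skipped and reported.
#'
#' @param obs observation tibble for one domain-mutation pair (columns
#'   `window_start`, `nc_wt`, `nc_mut`).
#' @param p_cutoff significance cut-off.
#' @return number of windows with p at or below the cut-off.
#' @export
individual_pair_significance <- function(obs, p_cutoff = 0.001) {
  windows <- split(obs, obs$window_start)
  skipped <- 0L
  n_sig <- 0L
  for (w in windows) {
    if (nrow(w) < 2) {
      skipped <- skipped + 1L
      next
    }
    if (mw_test(w$nc_wt, w$nc_mut) <= p_cutoff) n_sig <- n_sig + 1L
  }
  if (skipped > 0) {
    message(sprintf(
      "individual_pair_significance: %d window(s) with <2 replicates skipped",
      skipped
    ))
  }
  n_sig
}

#' Score and classify all domain-mutation pairs
#'
#' The main mutation-centred analysis: collapses peptide pairs, computes
#' the enrichment score and Mann-Whitney p value per (bait, mutation), and
#' classifies the effect direction at the chosen cut-off. A
#' Benjamini-Hochberg adjusted column (`fdr`) is reported for reference but
#' plays no role in the classification, which uses the raw p cut-off.
#'
#' @inheritParams collapse_pairs
#' @param p_cutoff significance cut-off for the direction call.
#' @return a `ppd_mutscan` tibble: `bait_id`, `protein_id`, `mutation`,
#'   `n_obs`, `enrichment_score`, `p_value`, `fdr`, `direction`,
#'   `n_significant_individual_pairs`.
#' @export
mutation_scan <- function(merged, design, p_cutoff = 0.001) {
  obs <- collapse_pairs(merged, design)
  out <- obs %>%
    dplyr::group_by(.data$bait_id, .data$protein_id, .data$mutation) %>%
    dplyr::summarise(
      n_obs = dplyr::n(),
      enrichment_score = enrichment_score(.data$nc_wt, .data$nc_mut),
      p_value = mw_test(.data$nc_wt, .data$nc_mut),
      n_significant_individual_pairs = individual_pair_significance(
        dplyr::pick("window_start", "nc_wt", "nc_mut"), p_cutoff = p_cutoff
      ),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      fdr = stats::p.adjust(.data$p_value, method = "BH"),
      direction = classify_direction(
        .data$enrichment_score, .data$p_value, p_cutoff = p_cutoff
      )
    ) %>%
    dplyr::relocate("fdr", .after = "p_value")
  attr(out, "p_cutoff") <- p_cutoff
  class(out) <- c("ppd_mutscan", class(out))
  out
}
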
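# Four-criterion confidence scoring of enriched peptides: (i) occurrence in
# replicate selections, (ii) overlap with another enriched peptide from the
# same protein, (iii) match to the bait's motif consensus, (iv) count
# support. Peptides meeting all four criteria are high confidence, two or
# three medium, otherwise low.

#' Index designed peptides by protein and window
#'
#' Maps every designed peptide (wild-type and mutant) to its source protein
#' and window coordinates; used for overlap computation and wt/mut pairing.
#'
#' @param design design tibble from [design_library()].
#' @param peptide_len window length used in the design.
#' @return tibble `peptide`, `protein_id`, `window_start`, `window_end`.
#' @export
design_peptide_index <- function(design, peptide_len = NULL) {
  if (is.null(peptide_len)) peptide_len <- nchar(design$wt_peptide[1])
  dplyr::bind_rows(
    dplyr::transmute(design, peptide = .data$wt_peptide,
                     protein_id = .data$protein_id,
                     window_start = .data$window_start),
    dplyr::transmute(design, peptide = .data$mut_peptide,
                     protein_id = .data$protein_id,
                     window_start = .data$window_start)
  ) %>%
    dplyr::distinct() %>%
    dplyr::mutate(window_end = .data$window_start + peptide_len - 1L)
}

#' Score enriched peptides on the four confidence criteria
#'
#' @param merged merged count tibble (`bait_id`, `peptide`, `replicate`,
#'   `merged_count`) from [normalise_and_merge()].
#' @param design design tibble linking peptides to proteins and windows.
#' @param motifs tibble `bait_id`, `consensus`; a bait without a motif model
#'   evaluates criterion (iii) false with a warning.
#' @param r_min minimum number of replicates a peptide must be observed in.
#' @param o_min minimum residue overlap with another enriched peptide of the
#'   same protein.
#' @param c_min count-support threshold; defaults to the median merged
#'   count of the retained peptides within each bait.
#' @return tibble with one row per (bait, peptide): protein/window columns,
#'   the four criterion flags, `score` (0-4) and `confidence_class`
#'   (low/medium/high).
#' @export
score_hits <- function(merged, design, motifs, r_min = 2, o_min = 4,
                       c_min = NULL) {
  idx <- design_peptide_index(design)
  per_pep <- merged %>%
    dplyr::filter(.data$merged_count > 0) %>%
    dplyr::group_by(.data$bait_id, .data$peptide) %>%
    dplyr::summarise(
      n_replicates = dplyr::n_distinct(.data$replicate),
      mean_merged = mean(.data$merged_count),
      .groups = "drop"
    ) %>%
    dplyr::left_join(idx, by = "peptide", relationship = "many-to-many")

  unmatched <- is.na(per_pep$protein_id)
  if (any(unmatched)) {
    warn(sprintf(
      "%d enriched peptide(s) not in the design were ignored", sum(unmatched)
    ))
    per_pep <- per_pep[!unmatched, , drop = FALSE]
  }
  motif_map <- setNames(motifs$consensus, motifs$bait_id)

  per_pep %>%
    dplyr::group_by(.data$bait_id) %>%
    dplyr::mutate(
      c_min_used = if (is.null(c_min)) median(.data$mean_merged) else c_min
    ) %>%
    dplyr::group_by(.data$bait_id, .data$protein_id) %>%
    dplyr::mutate(
      peptide_overlap = vapply(seq_len(dplyr::n()), function(i) {
        ov <- pmin(.data$window_end[i], .data$window_end[-i]) -
          pmax(.data$window_start[i], .data$window_start[-i]) + 1
        keep <- .data$peptide[-i] != .data$peptide[i]
        any(ov[keep] >= o_min)
      }, logical(1))
    ) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      replicate_occurrence = .data$n_replicates >= r_min,
      motif_match = purrr::map2_lgl(.data$bait_id, .data$peptide, function(b, p) {
        cons <- motif_map[b]
        if (is.na(cons)) {
          warn(sprintf("No motif model for bait '%s'; criterion set to FALSE", b))
          return(FALSE)
        }
        nrow(scan_motif(p, cons)) > 0
      }),
      count_support = .data$mean_merged >= .data$c_min_used,
      score = as.integer(.data$replicate_occurrence) +
        as.integer(.data$peptide_overlap) +
        as.integer(.data$motif_match) +
        as.integer(.data$count_support),
      confidence_class = confidence_class(.data$score)
    ) %>%
    dplyr::select(
      "bait_id", "peptide", "protein_id", "window_start", "window_end",
      "replicate_occurrence", "peptide_overlap", "motif_match",
      "count_support", "score", "confidence_class"
    )
}

#' Map a 0-4 confidence score to its class
#'
#' @param score integer vector of criterion counts.
#' @return factor: high (score 4), medium (2 or 3), low (0 or 1).
#' @export
confidence_class <- function(score) {
  stopifnot(all(score %in% 0:4))
  factor(
    ifelse(score == 4, "high", ifelse(score >= 2, "medium", "low")),
    levels = c("low", "medium", "high")
  )
}
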
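# Enrichment of previously reported protein-protein interactions among the
# selection hits, relative to the searchable bait x prey background.

#' Fold-enrichment of known interactions among hits
#'
#' Ratio of the known-interaction fraction among observed hits to the
#' known-interaction fraction in the searchable background, reported to two
#' decimals.
#'
#' @param observed_known,observed_total known and total unique
#'   protein-protein pairs among the selection hits.
#' @param background_known,background_total known and total possible unique
#'   bait-prey pairs in the library setting.
#' @return the fold-enrichment (2 decimals).
#' @export
enrichment_ratio <- function(observed_known, observed_total,
                             background_known, background_total) {
  stopifnot(
    observed_known <= observed_total, background_known <= background_total,
    observed_total > 0, background_total > 0
  )
  if (background_known == 0) {
    abort("Enrichment undefined: no known interactions in the background")
  }
  round(
    (observed_known / observed_total) / (background_known / background_total),
    2
  )
}

#' Count possible unique bait-prey pairs excluding self-binding
#'
#' @param baits,preys character vectors of protein accessions (deduplicated
#'   at the protein level).
#' @return `|baits| * |preys|` minus the pairs where bait and prey are the
#'   same protein.
#' @export
background_pairs <- function(baits, preys) {
  stopifnot(length(baits) > 0, length(preys) > 0)
  baits <- unique(baits)
  preys <- unique(preys)
  length(baits) * length(preys) - length(intersect(baits, preys))
}

#' Enrichment of known interactions for observed hit pairs
#'
#' Convenience wrapper taking explicit pair lists: hits and known
#' interactions as two-column data frames of accessions (bait, prey; order
#' within a pair is ignored).
#'
#' @param hits data frame of observed bait-prey pairs.
#' @param known data frame of previously reported pairs.
#' @param baits,preys accession vectors defining the searchable background.
#' @return one-row tibble: `observed_known`, `observed_total`,
#'   `background_known`, `background_total`, `enrichment`.
#' @export
ppi_enrichment <- function(hits, known, baits, preys) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  hit_keys <- unique(key(hits[[1]], hits[[2]]))
  known_keys <- unique(key(known[[1]], known[[2]]))
  bg_total <- background_pairs(baits, preys)
  bg <- tidyr::crossing(bait = unique(baits), prey = unique(preys)) %>%
    dplyr::filter(.data$bait != .data$prey)
  bg_known <- sum(unique(key(bg$bait, bg$prey)) %in% known_keys)
  tibble(
    observed_known = sum(hit_keys %in% known_keys),
    observed_total = length(hit_keys),
    background_known = bg_known,
    background_total = bg_total,
    enrichment = enrichment_ratio(
      sum(hit_keys %in% known_keys), length(hit_keys), bg_known, bg_total
    )
  )
}
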
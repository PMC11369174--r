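# Design of tiled wild-type/mutant peptide-pair libraries over disordered
# regions. Each missense variant is represented by paired peptides (wild type
# and mutant, identical except at the variant position) on every tiling
# window that overlaps the variant, so a single selection can discriminate
# allele binding preferences.

#' Replace cysteines by alanines in a peptide
#'
#' Displayed peptides must not form disulphide bridges with the phage coat,
#' so every cysteine in the design (wild-type and mutant alike) is replaced
#' by alanine before reverse translation.
#'
#' @param seq amino-acid string using the 20 canonical one-letter codes.
#' @return the sanitised peptide, same length as the input.
#' @examples
#' sanitize_peptide("ACDEFC") # "AADEFA"
#' @export
sanitize_peptide <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1, nzchar(seq))
  assert_residues(seq, "peptide")
  gsub("C", "A", seq, fixed = TRUE)
}

#' Tile a disordered region with wild-type/mutant peptide pairs
#'
#' Windows of `peptide_len` residues are placed at `step`-residue offsets
#' along the region. Every window that overlaps a variant position yields a
#' peptide pair: the wild-type window sequence and the same window with the
#' substitution applied. When several variants fall inside one window, one
#' mutant peptide is generated per variant so each designed peptide carries
#' a single mutation. Both members are cysteine-sanitised.
#'
#' If the trailing end of the region holds a variant that no full-grid
#' window reaches, one extra window anchored to the region end is added so
#' terminal variants are not lost.
#'
#' @param region a list or one-row data frame with `protein_id`, `start`,
#'   `end` (1-based inclusive residue coordinates) and `sequence`.
#' @param variants data frame of variants on this protein with columns
#'   `protein_id`, `position`, `wt_aa`, `mut_aa` and optionally
#'   `pathogenicity`, `origin`, `disease_categories`. `wt_aa`/`mut_aa` may be
#'   multi-residue strings of equal length for delins-type substitutions.
#' @param peptide_len window length in residues.
#' @param step offset between consecutive windows in residues.
#' @return a tibble with one row per (window, variant) pair: `protein_id`,
#'   `window_start` (absolute), `position`, `wt_aa`, `mut_aa`, `mutation`,
#'   `wt_peptide`, `mut_peptide` plus any pathogenicity/origin/category
#'   columns present in `variants`.
#' @export
tile_region <- function(region, variants, peptide_len = 16, step = 4) {
  region <- as.list(region)
  stopifnot(peptide_len > step, step >= 1)
  seq_len_region <- nchar(region$sequence)
  if (seq_len_region != region$end - region$start + 1) {
    abort(sprintf(
      "Region %s %d-%d: sequence length %d does not match coordinates",
      region$protein_id, region$start, region$end, seq_len_region
    ))
  }
  variants <- dplyr::filter(variants, .data$protein_id == region$protein_id)
  empty <- design_tbl_prototype(variants)
  if (nrow(variants) == 0) return(empty)
  if (seq_len_region < peptide_len) {
    warn(sprintf(
      "Region %s %d-%d is shorter than peptide_len (%d); no peptides designed",
      region$protein_id, region$start, region$end, peptide_len
    ))
    return(empty)
  }

  # validate variants against the region sequence
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    k <- nchar(v$wt_aa)
    if (nchar(v$mut_aa) != k) {
      abort(sprintf(
        "Variant %s:%d %s>%s: substitution strings differ in length",
        v$protein_id, v$position, v$wt_aa, v$mut_aa
      ))
    }
    rel <- v$position - region$start + 1
    if (rel < 1 || rel + k - 1 > seq_len_region) {
      abort(sprintf(
        "Variant %s:%d lies outside region %d-%d",
        v$protein_id, v$position, region$start, region$end
      ))
    }
    found <- substr(region$sequence, rel, rel + k - 1)
    if (found != v$wt_aa) {
      abort(sprintf(
        "Variant %s:%d expects wild-type '%s' but region sequence has '%s'",
        v$protein_id, v$position, v$wt_aa, found
      ))
    }
  }

  grid_starts <- seq(1, seq_len_region - peptide_len + 1, by = step)
  grid_cover <- function(pos_rel, span) {
    grid_starts[grid_starts <= pos_rel + span - 1 &
                grid_starts + peptide_len - 1 >= pos_rel]
  }
  # anchored terminal window, only when it rescues an otherwise lost variant
  anchor <- seq_len_region - peptide_len + 1
  need_anchor <- FALSE
  if (!anchor %in% grid_starts) {
    for (i in seq_len(nrow(variants))) {
      rel <- variants$position[i] - region$start + 1
      span <- nchar(variants$wt_aa[i])
      if (length(grid_cover(rel, span)) == 0 &&
          rel >= anchor && rel + span - 1 <= seq_len_region) {
        need_anchor <- TRUE
      }
    }
  }

  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    rel <- v$position - region$start + 1
    span <- nchar(v$wt_aa)
    starts <- grid_cover(rel, span)
    if (need_anchor && anchor <= rel + span - 1 &&
        anchor + peptide_len - 1 >= rel) {
      starts <- sort(unique(c(starts, anchor)))
    }
    # windows must contain the full substitution span
    starts <- starts[starts <= rel & starts + peptide_len - 1 >= rel + span - 1]
    for (s in starts) {
      wt_window <- substr(region$sequence, s, s + peptide_len - 1)
      off <- rel - s + 1
      mut_window <- paste0(
        substr(wt_window, 1, off - 1), v$mut_aa,
        substr(wt_window, off + span, peptide_len)
      )
      wt_pep <- sanitize_peptide(wt_window)
      mut_pep <- sanitize_peptide(mut_window)
      if (wt_pep == mut_pep) {
        warn(sprintf(
          "Variant %s:%d %s>%s collides with cysteine sanitisation; pair dropped",
          v$protein_id, v$position, v$wt_aa, v$mut_aa
        ))
        next
      }
      row <- tibble(
        protein_id = v$protein_id,
        window_start = as.integer(region$start + s - 1),
        position = as.integer(v$position),
        wt_aa = v$wt_aa,
        mut_aa = v$mut_aa,
        mutation = paste0(v$wt_aa, v$position, v$mut_aa),
        wt_peptide = wt_pep,
        mut_peptide = mut_pep
      )
      for (extra in intersect(
        c("pathogenicity", "origin", "disease_categories"), names(v)
      )) {
        row[[extra]] <- v[[extra]]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows)
}

design_tbl_prototype <- function(variants) {
  out <- tibble(
    protein_id = character(), window_start = integer(), position = integer(),
    wt_aa = character(), mut_aa = character(), mutation = character(),
    wt_peptide = character(), mut_peptide = character()
  )
  for (extra in intersect(
    c("pathogenicity", "origin", "disease_categories"), names(variants)
  )) {
    out[[extra]] <- variants[[extra]][0]
  }
  out
}

#' Ranked codon table for expression in E. coli
#'
#' Codons per residue ordered by K-12 usage; the reverse translator picks
#' the first codon that does not complete a forbidden restriction site and
#' falls back to lower-ranked codons at offending junctions.
#'
#' @return named list of character vectors, one per amino acid.
#' @export
ecoli_codon_table <- function() {
  list(
    A = c("GCG", "GCC", "GCA", "GCT"),
    R = c("CGT", "CGC", "CGG"),
    N = c("AAC", "AAT"),
    D = c("GAT", "GAC"),
    C = c("TGC", "TGT"),
    Q = c("CAG", "CAA"),
    E = c("GAA", "GAG"),
    G = c("GGC", "GGT", "GGG"),
    H = c("CAT", "CAC"),
    I = c("ATT", "ATC", "ATA"),
    L = c("CTG", "TTA", "CTC"),
    K = c("AAA", "AAG"),
    M = "ATG",
    F = c("TTT", "TTC"),
    P = c("CCG", "CCA", "CCT"),
    S = c("AGC", "TCT", "TCC"),
    T = c("ACC", "ACT", "ACG"),
    W = "TGG",
    V = c("GTG", "GTT", "GTC"),
    Y = c("TAT", "TAC")
  )
}

#' Reverse-translate a peptide avoiding forbidden restriction sites
#'
#' Deterministic greedy choice of the highest-ranked codon for each residue,
#' with local backtracking whenever appending a codon would create one of
#' the forbidden DNA substrings (checked across codon boundaries). The
#' default forbidden site is the SmaI recognition sequence CCCGGG, which
#' must not appear in the cloning insert.
#'
#' @param peptide sanitised amino-acid string.
#' @param codon_usage named list of ranked codon vectors per residue.
#' @param forbidden character vector of DNA substrings that must not occur.
#' @return a DNA string whose translation equals `peptide`.
#' @export
reverse_translate <- function(peptide, codon_usage = ecoli_codon_table(),
                              forbidden = "CCCGGG") {
  chars <- assert_residues(peptide, "peptide")
  n <- length(chars)
  choice <- integer(n)   # rank currently tried at each position
  dna <- character(n)
  has_forbidden <- function(s) {
    any(vapply(forbidden, function(f) grepl(f, s, fixed = TRUE), logical(1)))
  }
  i <- 1
  while (i <= n) {
    ranks <- codon_usage[[chars[i]]]
    if (is.null(ranks)) {
      abort(sprintf("No codons for residue '%s'", chars[i]))
    }
    placed <- FALSE
    k <- choice[i] + 1
    while (k <= length(ranks)) {
      candidate <- paste0(paste0(dna[seq_len(i - 1)], collapse = ""), ranks[k])
      if (!has_forbidden(candidate)) {
        dna[i] <- ranks[k]
        choice[i] <- k
        placed <- TRUE
        break
      }
      k <- k + 1
    }
    if (placed) {
      i <- i + 1
    } else {
      choice[i] <- 0
      i <- i - 1
      if (i < 1) {
        abort("Reverse translation cannot satisfy the forbidden-site constraint")
      }
      # force the previous position to advance past its current codon
    }
  }
  paste0(dna, collapse = "")
}

#' Build the full peptide-pair design over a set of regions
#'
#' Convenience wrapper: tiles every region with its variants, then
#' reverse-translates each unique peptide into an encoding oligo.
#'
#' @param regions data frame with `protein_id`, `start`, `end` and either a
#'   `sequence` column or a `proteome` to cut the region sequence from.
#' @param variants variant table (see [tile_region()]).
#' @param proteome optional tibble with `protein_id`, `sequence` (full-length
#'   protein sequences, e.g. from [read_proteome()]).
#' @param peptide_len,step tiling geometry (see [tile_region()]).
#' @param codon_usage,forbidden reverse-translation settings
#'   (see [reverse_translate()]).
#' @return design tibble: one row per wild-type/mutant peptide pair with
#'   `wt_oligo` and `mut_oligo` columns appended.
#' @export
design_library <- function(regions, variants, proteome = NULL,
                           peptide_len = 16, step = 4,
                           codon_usage = ecoli_codon_table(),
                           forbidden = "CCCGGG") {
  if (!"sequence" %in% names(regions)) {
    if (is.null(proteome)) {
      abort("Either regions$sequence or a proteome must be supplied")
    }
    regions <- regions %>%
      dplyr::left_join(
        dplyr::select(proteome, "protein_id", full_sequence = "sequence"),
        by = "protein_id"
      ) %>%
      dplyr::mutate(
        sequence = substr(.data$full_sequence, .data$start, .data$end)
      ) %>%
      dplyr::select(-"full_sequence")
  }
  covered <- rep(FALSE, nrow(variants))
  design <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    inside <- variants$protein_id == r$protein_id &
      variants$position >= r$start &
      variants$position + nchar(variants$wt_aa) - 1 <= r$end
    covered[inside] <<- TRUE
    if (!any(inside)) return(design_tbl_prototype(variants))
    tile_region(r, variants[inside, ], peptide_len = peptide_len, step = step)
  })
  if (any(!covered)) {
    warn(sprintf(
      "%d variant(s) fall outside every supplied region and were skipped",
      sum(!covered)
    ))
  }
  if (nrow(design) == 0) return(design)
  peps <- unique(c(design$wt_peptide, design$mut_peptide))
  oligos <- setNames(
    vapply(peps, reverse_translate, character(1),
           codon_usage = codon_usage, forbidden = forbidden),
    peps
  )
  design %>%
    dplyr::mutate(
      wt_oligo = unname(oligos[.data$wt_peptide]),
      mut_oligo = unname(oligos[.data$mut_peptide])
    )
}

#' Summarise a peptide-pair design
#'
#' Counts are deduplicated: a wild-type peptide shared by several mutant
#' partners is counted once, and percentages are computed on unique
#' mutations, not on design rows.
#'
#' @param designs design tibble from [design_library()] or [tile_region()].
#' @return one-row tibble: `n_mutations`, `n_prey_proteins`,
#'   `n_unique_peptides`, `n_wt_peptides`, `n_pairs`, `pct_pathogenic`,
#'   `pct_somatic` (percentages, 1 decimal) and a `disease_category_counts`
#'   list-column (a mutation with more than one category is tallied as
#'   "mixed").
#' @export
summarize_design <- function(designs) {
  stopifnot(nrow(designs) > 0)
  muts <- designs %>%
    dplyr::distinct(
      .data$protein_id, .data$position, .data$wt_aa, .data$mut_aa,
      dplyr::across(dplyr::any_of(
        c("pathogenicity", "origin", "disease_categories")
      ))
    )
  n_mut <- nrow(muts)
  pct <- function(x) round(100 * sum(x) / n_mut, 1)
  pct_path <- if ("pathogenicity" %in% names(muts)) {
    pct(muts$pathogenicity %in% c("pathogenic", "likely_pathogenic"))
  } else NA_real_
  pct_som <- if ("origin" %in% names(muts)) {
    pct(muts$origin == "somatic")
  } else NA_real_
  cat_counts <- if ("disease_categories" %in% names(muts)) {
    labels <- vapply(muts$disease_categories, function(x) {
      cats <- unlist(strsplit(as.character(x), ";", fixed = TRUE))
      cats <- unique(cats[nzchar(cats)])
      if (length(cats) > 1) "mixed" else if (length(cats) == 1) cats else NA_character_
    }, character(1))
    tab <- table(labels, useNA = "no")
    list(setNames(as.integer(tab), names(tab)))
  } else list(NULL)
  tibble(
    n_mutations = n_mut,
    n_prey_proteins = dplyr::n_distinct(designs$protein_id),
    n_unique_peptides = dplyr::n_distinct(
      c(designs$wt_peptide, designs$mut_peptide)
    ),
    n_wt_peptides = dplyr::n_distinct(designs$wt_peptide),
    n_pairs = nrow(dplyr::distinct(designs, .data$wt_peptide, .data$mut_peptide)),
    pct_pathogenic = pct_path,
    pct_somatic = pct_som,
    disease_category_counts = cat_counts
  )
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences; the record identifier
#'   (up to the first whitespace) becomes `protein_id`.
#' @return tibble with `protein_id` and `sequence`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble(
    protein_id = sub("\\s.*$", "", names(aa)),
    sequence = as.character(aa)
  )
}
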
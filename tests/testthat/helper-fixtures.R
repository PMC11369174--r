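# Small in-code fixtures shared across test files.

# A minimal one-protein design: 30-residue region, one interior SNV.
mini_region <- function(seq = NULL) {
  if (is.null(seq)) {
    seq <- paste0(rep("ADEHKPQRST", 3), collapse = "")
  }
  list(protein_id = "P1", start = 1L, end = nchar(seq), sequence = seq)
}

mini_variant <- function(position = 15, wt = NULL, mut = "W",
                         seq = mini_region()$sequence) {
  if (is.null(wt)) wt <- substr(seq, position, position)
  tibble::tibble(
    protein_id = "P1", position = as.integer(position),
    wt_aa = wt, mut_aa = mut
  )
}

# A hand-built merged count table for one bait: two windows x two
# replicates of a single wild-type/mutant pair.
mini_merged <- function(nc_wt = c(100, 120, 90, 110),
                        nc_mut = c(10, 8, 12, 9)) {
  design <- mini_design()
  tibble::tibble(
    bait_id = "B1",
    peptide = rep(c(design$wt_peptide[1:2], design$mut_peptide[1:2]), 2),
    replicate = rep(1:2, each = 4),
    merged_count = c(nc_wt[1:2], nc_mut[1:2], nc_wt[3:4], nc_mut[3:4])
  )
}

mini_design <- function() {
  tile_region(mini_region(), mini_variant())
}
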
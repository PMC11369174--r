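# Synthetic-data generator: a toy proteome with planted motif instances, a
# variant set with planted effect classes, overdispersed replicate
# selection count tables and noisy polarisation curves -- everything needed
# to exercise the pipeline end to end against known ground truth.

#' Simulation configuration
#'
#' Defaults emulate the screen's selection structure: four consecutive
#' selection days and five replicate selections per bait, with strongly
#' asymmetric binding (`delta = 0.9`) for motif-breaking/-creating variants
#' and negative-binomial count noise for the clonally amplified phage
#' pools.
#'
#' @param seed integer seed; all generators are pure functions of the
#'   configuration including this seed.
#' @param n_proteins number of prey proteins in the toy proteome.
#' @param region_len length of each disordered region segment (residues).
#' @param motif bait consensus planted in the regions.
#' @param n_per_class planted variants per effect class
#'   (motif_breaking_key, motif_creating, wildcard_neutral,
#'   flanking_neutral); a single integer applies to all four.
#' @param delta binding asymmetry in `[0, 1]`: the disfavoured member of an
#'   asymmetric pair keeps a fraction `1 - delta` of the binder's read
#'   propensity; 0 gives a null simulation.
#' @param depth sequencing reads per (replicate, day).
#' @param n_replicates,n_days replicate selections and selection days.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param binder_weight,background_weight relative read propensities of
#'   motif-containing and background peptides.
#' @param fp_noise_sd Gaussian noise on simulated polarisation values (mP).
#' @param bait_id label for the simulated bait.
#' @return a `ppd_sim_config` list.
#' @export
sim_config <- function(seed = 1, n_proteins = 8, region_len = 40,
                       motif = "[FILV]xFG",
                       n_per_class = 4, delta = 0.9, depth = 1e5,
                       n_replicates = 5, n_days = 4, dispersion = 5,
                       binder_weight = 50, background_weight = 0.01,
                       fp_noise_sd = 2, bait_id = "BAIT1") {
  classes <- c("motif_breaking_key", "motif_creating",
               "wildcard_neutral", "flanking_neutral")
  if (length(n_per_class) == 1 && is.null(names(n_per_class))) {
    n_per_class <- setNames(rep(n_per_class, 4), classes)
  }
  stopifnot(
    all(classes %in% names(n_per_class)), delta >= 0, delta <= 1,
    depth > 0, n_replicates >= 1, n_days >= 1, dispersion > 0,
    region_len >= 30
  )
  structure(
    list(
      seed = as.integer(seed), n_proteins = n_proteins,
      region_len = region_len, motif = motif, n_per_class = n_per_class,
      delta = delta, depth = depth, n_replicates = n_replicates,
      n_days = n_days, dispersion = dispersion,
      binder_weight = binder_weight, background_weight = background_weight,
      fp_noise_sd = fp_noise_sd, bait_id = bait_id
    ),
    class = "ppd_sim_config"
  )
}

# Residues used for background sequence: canonical minus C (sanitisation
# would rewrite it) and minus the residues that could complete the default
# motif's constrained positions by chance.
sim_background_alphabet <- function() {
  setdiff(AA_CANONICAL, c("C", "F", "G", "I", "L", "V"))
}

#' Simulate a toy proteome with planted motifs and variants
#'
#' Each variant lives in its own disordered-region segment. Per class:
#' motif-breaking variants substitute a constrained residue of a planted
#' instance, motif-creating variants complete an almost-instance,
#' wild-card variants substitute an unconstrained position inside an
#' instance, and flanking variants sit a few residues outside one.
#' Background sequence cannot match the motif by construction.
#'
#' @param config a [sim_config()].
#' @return list with `proteome` (tibble `protein_id`, `sequence`),
#'   `regions` (`protein_id`, `start`, `end`, `sequence`), `variants`
#'   (design-ready variant table) and `truth` (planted class and expected
#'   direction per variant).
#' @export
simulate_library <- function(config) {
  set.seed(config$seed)
  bg <- sim_background_alphabet()
  classes <- rep(names(config$n_per_class), config$n_per_class)
  n_var <- length(classes)
  protein_of <- rep(seq_len(config$n_proteins), length.out = n_var)
  rl <- config$region_len

  seg_rows <- list()
  var_rows <- list()
  for (i in seq_len(n_var)) {
    pid <- sprintf("SYNP%02d", protein_of[i])
    seg <- paste0(sample(bg, rl, replace = TRUE), collapse = "")
    ms <- sample(17:21, 1) # motif start, interior so >=3 windows cover it
    instance <- switch(classes[i],
      motif_creating = "LASG", # constrained position 3 not yet satisfied
      "LAFG"
    )
    substr(seg, ms, ms + 3) <- instance
    v <- switch(classes[i],
      motif_breaking_key = list(pos = ms + 2, wt = "F", mut = "S",
                                dir = "diminishing"),
      motif_creating = list(pos = ms + 2, wt = "S", mut = "F",
                            dir = "enhancing"),
      wildcard_neutral = list(pos = ms + 1, wt = "A", mut = "T",
                              dir = "neutral"),
      flanking_neutral = {
        pos <- ms - 4
        list(pos = pos, wt = substr(seg, pos, pos),
             mut = sample(setdiff(bg, substr(seg, pos, pos)), 1),
             dir = "neutral")
      }
    )
    seg_rows[[i]] <- tibble(
      protein_id = pid, rel_variant = v$pos, sequence = seg,
      class = classes[i], wt_aa = v$wt, mut_aa = v$mut,
      expected_direction = v$dir, motif_rel_start = ms
    )
  }
  segs <- dplyr::bind_rows(seg_rows) %>%
    dplyr::group_by(.data$protein_id) %>%
    dplyr::mutate(
      start = (dplyr::row_number() - 1L) * rl + 1L,
      end = .data$start + rl - 1L
    ) %>%
    dplyr::ungroup()

  proteome <- segs %>%
    dplyr::group_by(.data$protein_id) %>%
    dplyr::summarise(sequence = paste0(.data$sequence, collapse = ""),
                     .groups = "drop")
  regions <- segs %>%
    dplyr::select("protein_id", "start", "end", "sequence")
  variants <- segs %>%
    dplyr::transmute(
      protein_id = .data$protein_id,
      position = .data$start + .data$rel_variant - 1L,
      wt_aa = .data$wt_aa, mut_aa = .data$mut_aa,
      pathogenicity = "pathogenic", origin = "somatic",
      disease_categories = "synthetic"
    )
  truth <- segs %>%
    dplyr::transmute(
      protein_id = .data$protein_id,
      position = .data$start + .data$rel_variant - 1L,
      wt_aa = .data$wt_aa, mut_aa = .data$mut_aa,
      mutation = paste0(.data$wt_aa, .data$position, .data$mut_aa),
      class = .data$class,
      expected_direction = factor(
        .data$expected_direction,
        levels = c("diminishing", "neutral", "enhancing")
      ),
      motif_start = .data$start + .data$motif_rel_start - 1L
    )
  list(proteome = proteome, regions = regions, variants = variants,
       truth = truth)
}

#' Simulate replicate selection counts for a peptide-pair design
#'
#' Read propensities follow motif content: a peptide matching the bait
#' consensus has the binder baseline weight; its designed partner without a
#' match keeps a fraction `1 - delta` of that baseline (breaking variants
#' disfavour the mutant, creating variants the wild type); pairs where both
#' or neither member match are symmetric. Counts per (replicate, day) are
#' negative-binomial around `depth` times the normalised propensity.
#'
#' Optionally the counts are emitted as reads (reverse-translated oligos
#' with per-sample dual barcodes and uniform Q30 qualities) to exercise the
#' read-processing path end to end; use a small `depth` for that.
#'
#' @param design design tibble from [design_library()].
#' @param config a [sim_config()].
#' @param emit `"counts"` (default) or `"fastq"`.
#' @return list with `counts` (tibble `bait_id`, `peptide`, `replicate`,
#'   `day`, `count`), and for `emit = "fastq"` also `reads`, `scheme`,
#'   `adapter5`, `adapter3`.
#' @export
simulate_counts <- function(design, config, emit = c("counts", "fastq")) {
  emit <- match.arg(emit)
  set.seed(config$seed + 1L)
  motif <- parse_motif(config$motif)
  pairs <- design %>%
    dplyr::distinct(.data$wt_peptide, .data$mut_peptide) %>%
    dplyr::mutate(
      m_wt = purrr::map_lgl(.data$wt_peptide,
                            ~ nrow(scan_motif(.x, motif)) > 0),
      m_mut = purrr::map_lgl(.data$mut_peptide,
                             ~ nrow(scan_motif(.x, motif)) > 0)
    )
  b <- config$binder_weight
  w <- config$background_weight
  d <- config$delta
  pair_w <- pairs %>%
    dplyr::mutate(
      w_wt = ifelse(.data$m_wt, b, ifelse(.data$m_mut, b * (1 - d), w)),
      w_mut = ifelse(.data$m_mut, b, ifelse(.data$m_wt, b * (1 - d), w))
    )
  peptides <- tibble(
    peptide = c(pair_w$wt_peptide, pair_w$mut_peptide),
    weight = c(pair_w$w_wt, pair_w$w_mut)
  ) %>%
    dplyr::group_by(.data$peptide) %>%
    dplyr::summarise(weight = max(.data$weight), .groups = "drop")
  mu <- config$depth * peptides$weight / sum(peptides$weight)

  grid <- tidyr::crossing(
    replicate = seq_len(config$n_replicates),
    day = seq_len(config$n_days)
  )
  counts <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    tibble(
      bait_id = config$bait_id,
      peptide = peptides$peptide,
      replicate = grid$replicate[g],
      day = grid$day[g],
      count = rnbinom(nrow(peptides), mu = mu, size = config$dispersion)
    )
  }) %>%
    dplyr::filter(.data$count > 0)

  if (emit == "counts") return(list(counts = counts))

  # read emission: dual-barcoded, adapter-flanked oligos at uniform Q30
  oligo_of <- design %>%
    dplyr::distinct(peptide = .data$wt_peptide, oligo = .data$wt_oligo) %>%
    dplyr::bind_rows(dplyr::distinct(
      design, peptide = .data$mut_peptide, oligo = .data$mut_oligo
    )) %>%
    dplyr::distinct()
  if (anyNA(oligo_of$oligo)) abort("Design lacks oligos; run design_library()")
  adapter5 <- "GGTGGAGGATCG"
  adapter3 <- "GGAAGCGGAGGT"
  bases <- c("A", "C", "G", "T")
  bc <- function(i) paste0(bases[(i %/% c(64, 16, 4, 1)) %% 4 + 1], collapse = "")
  scheme <- grid %>%
    dplyr::mutate(
      sample_id = sprintf("R%dD%d", .data$replicate, .data$day),
      bait_id = config$bait_id,
      barcode5 = paste0("AC", vapply(dplyr::row_number(), bc, character(1))),
      barcode3 = paste0("TG", vapply(dplyr::row_number() + 97L, bc, character(1)))
    )
  expanded <- counts %>%
    dplyr::left_join(oligo_of, by = "peptide") %>%
    dplyr::left_join(scheme, by = c("bait_id", "replicate", "day")) %>%
    dplyr::slice(rep(seq_len(dplyr::n()), .data$count))
  reads <- tibble(
    read_id = sprintf("read%07d", seq_len(nrow(expanded))),
    seq = paste0(expanded$barcode5, adapter5, expanded$oligo,
                 adapter3, expanded$barcode3),
    qual = vapply(nchar(expanded$barcode5) + nchar(expanded$barcode3) +
                    nchar(adapter5) + nchar(adapter3) + nchar(expanded$oligo),
                  function(n) strrep("?", n), character(1)) # Phred 30
  )
  list(counts = counts, reads = reads, scheme = scheme,
       adapter5 = adapter5, adapter3 = adapter3)
}

#' Simulate saturation and displacement polarisation curves
#'
#' Forward models are the fitting equations: the ligand-depletion quadratic
#' for saturation, and the full three-species competitive equilibrium
#' (solved numerically) for displacement, plus Gaussian mP noise.
#'
#' @param kd_sat planted saturation K_D values (molar).
#' @param kd_comp planted competitor K_D values (molar); values far above
#'   the titrated range produce non-binding curves.
#' @param config a [sim_config()] (uses `seed` and `fp_noise_sd`).
#' @param probe_conc labelled probe concentration (molar).
#' @param probe_kd probe/protein K_D used for the displacement set (molar).
#' @param mp_free,mp_max polarisation of free and fully bound probe (mP).
#' @param n_points concentration points per dilution series.
#' @param n_reps technical replicates per point (measurements are made in
#'   technical triplicates).
#' @return list of two tibbles, `saturation` (`curve_id`, `kd_true`,
#'   `replicate`, `protein_conc`, `mp`) and `displacement` (`curve_id`,
#'   `kd_true`, `replicate`, `protein_conc`, `competitor_conc`, `mp`).
#' @export
simulate_fp_curves <- function(kd_sat, kd_comp, config,
                               probe_conc = 10e-9, probe_kd = 1e-6,
                               mp_free = 50, mp_max = 220, n_points = 12,
                               n_reps = 3) {
  set.seed(config$seed + 2L)
  sat <- purrr::imap_dfr(kd_sat, function(kd, i) {
    conc <- rep(kd * 2^seq(-6, 5, length.out = n_points), n_reps)
    mp <- mp_free + (mp_max - mp_free) * bound_fraction(conc, probe_conc, kd) +
      rnorm(length(conc), 0, config$fp_noise_sd)
    tibble(curve_id = sprintf("sat%02d", as.integer(i)), kd_true = kd,
           replicate = rep(seq_len(n_reps), each = n_points),
           protein_conc = conc, mp = mp)
  })
  protein_conc <- 2 * probe_kd # 1-2x the probe-complex K_D
  disp <- purrr::imap_dfr(kd_comp, function(kd, i) {
    conc1 <- 10^seq(-8, -2.5, length.out = n_points)
    fb <- vapply(conc1, function(itot) {
      competitive_bound_fraction(protein_conc, probe_conc, itot,
                                 probe_kd, kd)
    }, numeric(1))
    conc <- rep(conc1, n_reps)
    mp <- mp_free + (mp_max - mp_free) * rep(fb, n_reps) +
      rnorm(length(conc), 0, config$fp_noise_sd)
    tibble(curve_id = sprintf("disp%02d", as.integer(i)), kd_true = kd,
           replicate = rep(seq_len(n_reps), each = n_points),
           protein_conc = protein_conc, competitor_conc = conc, mp = mp)
  })
  list(saturation = sat, displacement = disp)
}

#' Bound probe fraction in a three-species competitive equilibrium
#'
#' Solves the mass balance for free protein with both the labelled probe
#' and the unlabelled competitor present, and returns the fraction of
#' probe in complex.
#'
#' @param p_tot,l_tot,i_tot total protein, probe and competitor (molar).
#' @param kd_probe,kd_comp dissociation constants (molar).
#' @return fraction of the probe bound to protein.
#' @export
competitive_bound_fraction <- function(p_tot, l_tot, i_tot,
                                       kd_probe, kd_comp) {
  f <- function(p) {
    l_free <- l_tot / (1 + p / kd_probe)
    i_free <- i_tot / (1 + p / kd_comp)
    p + p * l_free / kd_probe + p * i_free / kd_comp - p_tot
  }
  p_free <- stats::uniroot(f, c(0, p_tot), tol = 1e-15 * max(p_tot, 1e-12))$root
  l_free <- l_tot / (1 + p_free / kd_probe)
  (p_free * l_free / kd_probe) / l_tot
}
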
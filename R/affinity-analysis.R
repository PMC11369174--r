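# Fluorescence-polarisation affinity analytics: ligand-depletion
# (quadratic) saturation fits, logistic displacement fits on the log
# concentration axis, conversion of displacement IC50 values to competitor
# K_D with probe-occupancy correction, wild-type/mutant fold-changes with
# non-binder capping, and agreement scoring against phage enrichment
# scores.

#' Bound probe fraction under ligand depletion
#'
#' Physical root of the quadratic binding equation in total protein `p_tot`,
#' total probe `l_tot` and dissociation constant `kd`; valid when the probe
#' concentration is not negligible against `kd`.
#'
#' @param p_tot,l_tot,kd total protein, total probe and K_D, in the same
#'   (molar) units.
#' @return fraction of probe bound, in `[0, 1]`.
#' @export
bound_fraction <- function(p_tot, l_tot, kd) {
  s <- p_tot + l_tot + kd
  pl <- (s - sqrt(s^2 - 4 * p_tot * l_tot)) / 2
  pl / l_tot
}

#' Fit a saturation binding curve
#'
#' Least-squares fit of
#' `mP = mp_free + (mp_max - mp_free) * bound_fraction(P, L, kd)` to a
#' protein dilution series at fixed probe concentration.
#'
#' @param curve tibble with `protein_conc` (molar) and `mp`
#'   (millipolarisation); replicate rows are fitted together.
#' @param probe_conc fixed probe concentration (molar).
#' @return a `ppd_fp_fit` object with elements `kd`, `mp_free`, `mp_max`,
#'   `flagged` (degenerate or non-converged fit), `fit` (the `nls` object
#'   or `NULL`) and `data`.
#' @export
fit_saturation <- function(curve, probe_conc) {
  stopifnot(all(c("protein_conc", "mp") %in% names(curve)))
  if (nrow(curve) < 5) abort("At least 5 concentration points are required")
  out <- list(
    kd = NA_real_, mp_free = NA_real_, mp_max = NA_real_,
    flagged = TRUE, fit = NULL, data = curve, probe_conc = probe_conc,
    type = "saturation"
  )
  class(out) <- "ppd_fp_fit"
  span <- diff(range(curve$mp))
  if (span < 1e-8 * (abs(mean(curve$mp)) + 1)) {
    return(out) # flat series: no transition to fit
  }
  half <- min(curve$mp) + span / 2
  kd0 <- suppressWarnings(
    stats::approx(curve$mp, curve$protein_conc, xout = half, ties = mean)$y
  )
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(curve$protein_conc)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      mp ~ mp_free + (mp_max - mp_free) *
        bound_fraction(protein_conc, probe_conc, kd),
      data = curve,
      start = list(mp_free = min(curve$mp), mp_max = max(curve$mp), kd = kd0),
      lower = c(-Inf, -Inf, 1e-15),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  out$kd <- unname(cf["kd"])
  out$mp_free <- unname(cf["mp_free"])
  out$mp_max <- unname(cf["mp_max"])
  out$fit <- fit
  out$flagged <- out$kd <= 2e-15 ||
    out$kd > 100 * max(curve$protein_conc) ||
    abs(out$mp_max - out$mp_free) < 1e-6 * (abs(out$mp_free) + 1)
  out
}

#' Fit a competitive displacement curve
#'
#' Four-parameter logistic on the log10 competitor concentration:
#' `mP = bottom + (top - bottom) / (1 + 10^((log10(c) - log10(IC50)) * h))`.
#' The curve is flagged as non-binding when no displacement plateau is
#' reached within the titrated range: the fitted transition midpoint lies
#' above the highest tested concentration, or the fitted span is below
#' `min_span`.
#'
#' @param curve tibble with `competitor_conc` (molar, > 0) and `mp`.
#' @param min_span smallest fitted mP drop accepted as real displacement.
#' @return a `ppd_fp_fit` object with `ic50`, `non_binder`, `anomalous`
#'   (mP rising with competitor), `top`, `bottom`, `hill`.
#' @export
fit_displacement <- function(curve, min_span = 5) {
  stopifnot(all(c("competitor_conc", "mp") %in% names(curve)))
  if (nrow(curve) < 6) abort("At least 6 concentration points are required")
  rng <- range(curve$competitor_conc)
  if (rng[1] <= 0) abort("Competitor concentrations must be positive")
  if (log10(rng[2] / rng[1]) < 2) {
    warn("Competitor series spans less than 2 decades")
  }
  dat <- dplyr::mutate(curve, logc = log10(.data$competitor_conc))
  out <- list(
    ic50 = NA_real_, non_binder = TRUE, anomalous = FALSE,
    top = NA_real_, bottom = NA_real_, hill = NA_real_,
    flagged = FALSE, fit = NULL, data = curve, type = "displacement"
  )
  class(out) <- "ppd_fp_fit"
  # anomalous: polarisation increasing with competitor
  trend <- stats::coef(stats::lm(mp ~ logc, data = dat))[2]
  span_obs <- diff(range(dat$mp))
  if (trend > 0 && span_obs > min_span) {
    out$anomalous <- TRUE
    out$flagged <- TRUE
    return(out)
  }
  if (span_obs < min_span) {
    return(out) # flat: no displacement within the range
  }
  mid0 <- stats::median(dat$logc)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      mp ~ bottom + (top - bottom) / (1 + 10^((logc - logic50) * hill)),
      data = dat,
      start = list(bottom = min(dat$mp), top = max(dat$mp),
                   logic50 = mid0, hill = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out$flagged <- TRUE
    return(out)
  }
  cf <- coef(fit)
  ic50 <- 10^unname(cf["logic50"])
  out$top <- unname(cf["top"])
  out$bottom <- unname(cf["bottom"])
  out$hill <- unname(cf["hill"])
  out$fit <- fit
  span_fit <- out$top - out$bottom
  if (span_fit < min_span || ic50 > rng[2] || ic50 < rng[1] / 100) {
    return(out) # transition not resolved inside the titration
  }
  out$ic50 <- ic50
  out$non_binder <- FALSE
  out
}

#' Convert a displacement IC50 into a competitor K_D
#'
#' Correction for probe occupancy and protein depletion at the displacement
#' midpoint: the probe/protein complex without competitor is taken from the
#' quadratic binding equation, halved at 50% inhibition, and the free
#' competitor concentration at the midpoint enters
#' `K_D = I50 / (L50/kd_probe + P0/kd_probe + 1)`, where `L50` is the free
#' probe and `P0` the free protein at 0% inhibition. In the dilute limit
#' (probe and protein far below the probe K_D) the result approaches the
#' IC50 itself, and it never exceeds the IC50.
#'
#' @param ic50 fitted displacement midpoint (molar).
#' @param probe_conc total labelled probe concentration (molar).
#' @param probe_kd K_D of the probe/protein complex (molar).
#' @param protein_conc total protein concentration (molar).
#' @return the competitor dissociation constant (molar).
#' @export
ic50_to_kd <- function(ic50, probe_conc, probe_kd, protein_conc) {
  stopifnot(ic50 > 0, probe_conc > 0, probe_kd > 0, protein_conc > 0)
  s <- protein_conc + probe_conc + probe_kd
  pl0 <- (s - sqrt(s^2 - 4 * protein_conc * probe_conc)) / 2
  p0 <- protein_conc - pl0
  pl50 <- pl0 / 2
  l50 <- probe_conc - pl50
  p50 <- probe_kd * pl50 / l50
  i50 <- ic50 - (protein_conc - pl50 - p50) # free competitor at the midpoint
  if (i50 <= 0) {
    abort("IC50 below the protein-bound competitor concentration; no valid K_D")
  }
  i50 / (l50 / probe_kd + p0 / probe_kd + 1)
}

#' Wild-type/mutant affinity fold-change with non-binder capping
#'
#' `fold = kd_wt / kd_mut`, oriented so fold > 1 means the mutant binds
#' tighter (directly comparable to the sign of the enrichment score). When
#' one member shows no displacement, the unbounded change is capped at
#' `cap` (or `1/cap`), giving `|log2 fold| = log2(cap)` (4.3 for the
#' default cap of 20, reported to 1 decimal).
#'
#' @param kd_wt,kd_mut K_D values; use [non_binder()] for a peptide with no
#'   displacement. Vectorised.
#' @param cap fold-change cap applied on either side for non-binders.
#' @return tibble with `fold`, `log2_fold` (rounded to 1 decimal) and
#'   `capped`.
#' @export
fold_change <- function(kd_wt, kd_mut, cap = 20) {
  stopifnot(length(kd_wt) == length(kd_mut), cap > 1)
  both <- is_non_binder(kd_wt) & is_non_binder(kd_mut)
  if (any(both)) {
    abort("Fold-change undefined when both members are non-binders")
  }
  fold <- ifelse(
    is_non_binder(kd_wt), cap,
    ifelse(is_non_binder(kd_mut), 1 / cap, kd_wt / kd_mut)
  )
  tibble(
    fold = fold,
    log2_fold = round(log2(fold), 1),
    capped = is_non_binder(kd_wt) | is_non_binder(kd_mut)
  )
}

#' Attach fold-changes and phage-agreement calls to affinity records
#'
#' A record agrees with the phage selection when the affinity change is at
#' least `threshold`-fold in either direction (a capped non-binder change
#' always qualifies) and its direction matches the sign of the referenced
#' enrichment score.
#'
#' @param records tibble with `kd_wt`, `kd_mut` (non-binders as `NA`) and
#'   `enrichment_score`; further columns are carried through.
#' @param threshold minimum fold-difference counted as a real change.
#' @param cap non-binder fold cap (see [fold_change()]).
#' @return `records` with `fold`, `log2_fold`, `capped` and `agreement`
#'   columns; class `ppd_affinity`.
#' @export
score_agreement <- function(records, threshold = 2, cap = 20) {
  fc <- fold_change(records$kd_wt, records$kd_mut, cap = cap)
  out <- dplyr::bind_cols(records, fc) %>%
    dplyr::mutate(
      agreement = (.data$capped |
                     .data$fold >= .env$threshold |
                     .data$fold <= 1 / .env$threshold) &
        sign(.data$log2_fold) == sign(.data$enrichment_score)
    )
  class(out) <- c("ppd_affinity", class(out))
  out
}

#' Summarise phage/affinity agreement
#'
#' @inheritParams score_agreement
#' @return one-row tibble `n_agree`, `n_total`, `pct` (rounded to integer).
#'   Records without an enrichment score are excluded and reported.
#' @export
agreement_table <- function(records, threshold = 2, cap = 20) {
  if (nrow(records) == 0) {
    abort("No affinity records supplied")
  }
  missing_score <- is.na(records$enrichment_score)
  if (any(missing_score)) {
    message(sprintf(
      "agreement_table: %d record(s) without an enrichment score excluded",
      sum(missing_score)
    ))
    records <- records[!missing_score, , drop = FALSE]
  }
  scored <- score_agreement(records, threshold = threshold, cap = cap)
  tibble(
    n_agree = sum(scored$agreement),
    n_total = nrow(scored),
    pct = round(100 * sum(scored$agreement) / nrow(scored))
  )
}

#' Load the packaged wild-type/mutant affinity reference table
#'
#' A transcription of the published affinity validation panel: 24
#' wild-type/mutant peptide pairs against 15 bait domains measured by FP
#' displacement, plus the supplementary importin-alpha minor-pocket rows
#' and one pair without a phage score. `kd_*` values are in micromolar;
#' non-binders are `NA` with the `*_limit` column recording `nb`, and
#' bound-beyond-range values carry a `<` limit with the bounding value.
#'
#' @return tibble of affinity records; rows with `in_agreement_set = TRUE`
#'   form the 24-pair agreement panel (importin-alpha scored on its major,
#'   motif-cognate pocket).
#' @export
read_affinity_reference <- function() {
  path <- system.file("extdata", "affinity_reference.tsv", package = "mutppd")
  readr::read_tsv(path, comment = "#", show_col_types = FALSE) %>%
    dplyr::mutate(
      kd_wt = as.numeric(.data$kd_wt),
      kd_mut = as.numeric(.data$kd_mut)
    )
}
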
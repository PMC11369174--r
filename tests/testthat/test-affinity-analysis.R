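test_that("saturation fitting recovers a planted K_D from noiseless data", {
  kd <- 1e-6
  probe <- 10e-9
  conc <- kd * 2^seq(-6, 5, length.out = 12)
  curve <- tibble::tibble(
    protein_conc = conc,
    mp = 50 + 170 * bound_fraction(conc, probe, kd)
  )
  fit <- fit_saturation(curve, probe_conc = probe)
  expect_false(fit$flagged)
  expect_lt(abs(fit$kd - kd) / kd, 0.01)
  expect_lt(abs(fit$mp_free - 50), 0.5)
  expect_lt(abs(fit$mp_max - 220), 0.5)
  td <- tidy(fit)
  expect_identical(td$type, "saturation")
})

test_that("the quadratic model reduces to the hyperbola when protein >> probe", {
  kd <- 5e-6
  probe <- 1e-12 # vastly below kd: depletion negligible
  conc <- kd * 2^seq(-6, 5, length.out = 12)
  curve <- tibble::tibble(
    protein_conc = conc,
    mp = 50 + 170 * conc / (conc + kd) # simple hyperbolic forward model
  )
  fit <- fit_saturation(curve, probe_conc = probe)
  expect_lt(abs(fit$kd - kd) / kd, 0.02)
})

test_that("a flat polarisation series is flagged with no K_D", {
  curve <- tibble::tibble(
    protein_conc = 10^seq(-8, -4, length.out = 8), mp = rep(100, 8)
  )
  fit <- fit_saturation(curve, probe_conc = 10e-9)
  expect_true(fit$flagged)
  expect_true(is.na(fit$kd))
})

test_that("displacement fitting recovers a planted IC50", {
  ic50 <- 1e-5
  conc <- 10^seq(-8, -2.5, length.out = 12)
  mp <- 60 + (210 - 60) / (1 + 10^((log10(conc) - log10(ic50)) * 1))
  fit <- fit_displacement(tibble::tibble(competitor_conc = conc, mp = mp))
  expect_false(fit$non_binder)
  expect_lt(abs(fit$ic50 - ic50) / ic50, 0.01)
  # 2% of the dynamic range as noise, measured in technical triplicates
  conc3 <- rep(conc, 3)
  mp3 <- 60 + 150 / (1 + 10^((log10(conc3) - log10(ic50)) * 1))
  set.seed(601)
  fit2 <- fit_displacement(tibble::tibble(
    competitor_conc = conc3, mp = mp3 + rnorm(length(conc3), 0, 3)
  ))
  expect_lt(abs(fit2$ic50 - ic50) / ic50, 0.10)
})

test_that("curves without a resolved transition are non-binders", {
  conc <- 10^seq(-8, -2.5, length.out = 12)
  flat <- tibble::tibble(competitor_conc = conc, mp = rep(180, 12))
  expect_true(fit_displacement(flat)$non_binder)
  # transition far above the titrated range
  ic50 <- 1 # 1 M, way beyond 3 mM top concentration
  mp <- 60 + 150 / (1 + 10^((log10(conc) - log10(ic50)) * 1))
  out_of_range <- fit_displacement(tibble::tibble(competitor_conc = conc, mp = mp))
  expect_true(out_of_range$non_binder)
  rising <- tibble::tibble(competitor_conc = conc,
                           mp = 60 + 15 * log10(conc / min(conc)))
  fit <- fit_displacement(rising)
  expect_true(fit$anomalous)
})

test_that("IC50 to K_D conversion approaches the IC50 in the dilute limit", {
  # with probe and protein 1000-fold below the probe K_D the exact
  # conversion deviates from the IC50 by (L50 + P0)/K_D plus the
  # free-competitor correction, about 0.2% here
  probe_kd <- 1e-6
  kd <- ic50_to_kd(1e-5, probe_conc = probe_kd / 1000,
                   probe_kd = probe_kd, protein_conc = probe_kd / 1000)
  expect_lt(abs(kd / 1e-5 - 1), 0.0025)
  expect_lte(kd, 1e-5)
  expect_error(ic50_to_kd(-1, 1e-8, 1e-6, 1e-6))
})

test_that("IC50 to K_D conversion inverts the competitive equilibrium", {
  probe <- 10e-9
  probe_kd <- 1e-6
  protein <- 2e-6
  for (kd_true in c(1e-7, 1e-6, 1e-5)) {
    ic50 <- equilibrium_ic50(protein, probe, probe_kd, kd_true)
    kd_est <- ic50_to_kd(ic50, probe, probe_kd, protein)
    expect_lt(abs(kd_est - kd_true) / kd_true, 0.05)
    expect_lte(kd_est, ic50)
  }
})

test_that("the conversion is monotone in IC50 and in protein concentration", {
  base <- ic50_to_kd(1e-5, 1e-8, 1e-6, 1e-6)
  expect_gt(ic50_to_kd(2e-5, 1e-8, 1e-6, 1e-6), base)
  expect_lt(ic50_to_kd(1e-5, 1e-8, 1e-6, 2e-6), base)
})

test_that("fold-change orientation, reciprocity and capping", {
  fc <- fold_change(0.9, 23)
  expect_lt(fc$fold, 1) # mutant binds weaker
  expect_equal(fc$fold, 0.9 / 23)
  expect_false(fc$capped)
  # reciprocity for numeric inputs
  expect_equal(fold_change(0.9, 23)$fold * fold_change(23, 0.9)$fold, 1)
  # non-binder capping on either side
  cap_wt <- fold_change(non_binder(), 39)
  expect_equal(cap_wt$fold, 20)
  expect_equal(cap_wt$log2_fold, 4.3)
  expect_true(cap_wt$capped)
  cap_mut <- fold_change(135, non_binder())
  expect_equal(cap_mut$log2_fold, -4.3)
  expect_equal(fold_change(5, 5)$log2_fold, 0)
  expect_error(fold_change(non_binder(), non_binder()), "both members")
})

test_that("the packaged affinity panel reproduces the published agreement", {
  ref <- read_affinity_reference()
  panel <- dplyr::filter(ref, in_agreement_set)
  expect_equal(nrow(panel), 24)
  tab <- agreement_table(panel)
  expect_equal(tab$n_agree, 19)
  expect_equal(tab$pct, 79)
  # a sub-twofold change never counts as agreement: the deubiquitinase row
  usp7 <- dplyr::filter(panel, bait_id == "USP7_MATH")
  expect_false(score_agreement(usp7)$agreement)
  # order invariance
  shuffled <- panel[rev(seq_len(nrow(panel))), ]
  expect_equal(agreement_table(shuffled), tab)
  # records without a phage score are excluded and reported
  with_nd <- dplyr::filter(ref, in_agreement_set | bait_id == "KPNA7_ARM")
  expect_message(tab2 <- agreement_table(with_nd), "excluded")
  expect_equal(tab2$n_total, 24)
  expect_error(agreement_table(ref[0, ]), "No affinity records")
})

test_that("simulated polarisation curves round-trip through the fitters", {
  cfg <- sim_config(seed = 41, fp_noise_sd = 0)
  curves <- simulate_fp_curves(
    kd_sat = c(5e-7, 2e-6), kd_comp = c(2e-6, 2e-5), cfg
  )
  for (cid in unique(curves$saturation$curve_id)) {
    cv <- dplyr::filter(curves$saturation, curve_id == cid)
    fit <- fit_saturation(cv, probe_conc = 10e-9)
    expect_lt(abs(fit$kd - cv$kd_true[1]) / cv$kd_true[1], 0.001)
  }
  for (cid in unique(curves$displacement$curve_id)) {
    cv <- dplyr::filter(curves$displacement, curve_id == cid)
    fit <- fit_displacement(cv)
    kd <- ic50_to_kd(fit$ic50, 10e-9, 1e-6, cv$protein_conc[1])
    expect_lt(abs(kd - cv$kd_true[1]) / cv$kd_true[1], 0.05)
  }
  # noisy recovery at the configured 2 mP noise level: individual runs
  # scatter by a few percent, so the typical (median) error over several
  # generator seeds is the meaningful recovery statistic
  true_ic <- equilibrium_ic50(2e-6, 1e-8, 1e-6, 1e-5)
  errs <- vapply(40:44, function(s) {
    noisy <- simulate_fp_curves(kd_sat = 1e-6, kd_comp = 1e-5,
                                sim_config(seed = s, fp_noise_sd = 2))
    abs(fit_displacement(noisy$displacement)$ic50 - true_ic) / true_ic
  }, numeric(1))
  expect_lt(median(errs), 0.10)
  expect_true(all(errs < 0.25))
  # a competitor far above the titration range reads as non-binding
  nb <- simulate_fp_curves(kd_sat = 1e-6, kd_comp = 1,
                           sim_config(seed = 42, fp_noise_sd = 2))
  expect_true(fit_displacement(nb$displacement)$non_binder)
})
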
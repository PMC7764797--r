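# Trial orchestration, phenotype arms, network qualification, mechanism
# comparison.

test_that("a CYP2C19 PM is fully protected from a pure CYP2C19 inhibitor", {
  # clamped-inhibitor DGI: with zero CYP2C19 activity the victim's remaining
  # clearance is untouched, so the DDI vanishes exactly
  ind <- fast_mix_individual()
  victim <- drug("victim", 300, fu = 1, kp_map = list(default = 1),
                 pathways = list(pathway("CYP2C19", "linear", cl_int = 1),
                                 pathway("CYP3A4", "linear", cl_int = 0.05)))
  perp <- clamped_inhibitor(list(inhibition("CYP2C19", "competitive",
                                            ki = "3.6 nM")))
  sp <- trial_spec("pm-dgi", victim,
                   dosing_regimen("victim", "iv_bolus", 30, 60),
                   perpetrator = perp,
                   perp_regimen = dosing_regimen("perp", "iv_bolus", 3, 0),
                   phenotypes = list(phenotype("CYP2C19", 0)),
                   t_end = 1500, extrapolate = TRUE, n_grid = 401)
  tr <- run_trial(sp, trial_library(ind, test_solver()))
  expect_equal(tr$ratios$auc_ratio, 1, tolerance = 0.005)
  # the same trial in an EM shows a real interaction
  sp_em <- sp; sp_em$phenotypes <- list()
  tr_em <- run_trial(sp_em, trial_library(ind, test_solver()))
  expect_gt(tr_em$ratios$auc_ratio, 1.5)
})

test_that("a perpetrator dosed at zero exposure leaves ratios at 1", {
  ind <- fast_mix_individual()
  victim <- cyp_victim(cl_int = 1)
  perp <- clamped_inhibitor(list(inhibition("CYP2C19", "competitive", ki = 1)))
  sp <- trial_spec("null-perp", victim,
                   dosing_regimen("victim", "iv_bolus", 30, 60),
                   perpetrator = perp,
                   perp_regimen = dosing_regimen("perp", "iv_bolus", 1e-12, 0),
                   t_end = 1000, extrapolate = TRUE, n_grid = 301)
  tr <- run_trial(sp, trial_library(ind, test_solver()))
  expect_equal(tr$ratios$auc_ratio, 1, tolerance = 1e-3)
  expect_equal(tr$ratios$cmax_ratio, 1, tolerance = 1e-3)
})

test_that("a perpetrator with no relevant inhibition warns and gives ratio 1", {
  ind <- fast_mix_individual()
  victim <- cyp_victim(cl_int = 1, enzyme = "CYP2C19")
  perp <- clamped_inhibitor(list(inhibition("CYP2D6", "competitive", ki = 0.1)))
  sp <- trial_spec("irrelevant-perp", victim,
                   dosing_regimen("victim", "iv_bolus", 30, 60),
                   perpetrator = perp,
                   perp_regimen = dosing_regimen("perp", "iv_bolus", 10, 0),
                   t_end = 1000, extrapolate = TRUE, n_grid = 301)
  expect_warning(tr <- run_trial(sp, trial_library(ind, test_solver())),
                 "no inhibition")
  expect_equal(tr$ratios$auc_ratio, 1, tolerance = 1e-3)
})

test_that("the qualification panel has the published 11-pair structure", {
  specs <- network_qualification_specs()
  expect_length(specs, 11)
  cats <- table(vapply(specs, function(s) attr(s, "category"), character(1)))
  expect_equal(as.integer(cats[c("strong CYP2C19", "strong CYP1A2",
                                 "moderate CYP2C19", "moderate CYP1A2")]),
               c(2L, 3L, 2L, 4L))
  # omeprazole trials dose both enantiomers at half the racemate dose
  fo <- specs[["fluvoxamine-omeprazole"]]
  expect_length(fo$victims, 2)
  expect_setequal(vapply(fo$victims, `[[`, character(1), "name"),
                  c("esomeprazole", "r-omeprazole"))
  doses <- vapply(fo$victim_regimens, `[[`, numeric(1), "dose_mg")
  expect_equal(doses, c(20, 20))
  # pair-specific constants are injected from the interaction library
  fluvo <- fo$perpetrators[[1]]
  k <- Filter(function(i) i$target_enzyme == "CYP2C19", fluvo$inhibitions)
  expect_equal(k[[1]]$ki, 0.0036)
  ft <- specs[["fluvoxamine-tizanidine"]]$perpetrators[[1]]
  k2 <- Filter(function(i) i$target_enzyme == "CYP1A2", ft$inhibitions)
  expect_equal(k2[[1]]$ki, 0.0008697)
})

test_that("stronger inhibitors produce larger caffeine AUC ratios", {
  # fluvoxamine (Ki 2.97 nM) vs mexiletine (Ki 0.28 µM) on caffeine, at the
  # network's dosing regimes
  specs <- network_qualification_specs()
  lib <- trial_library(solver = test_solver())
  r_strong <- run_trial(specs[["fluvoxamine-caffeine"]], lib)$ratios$auc_ratio
  r_mod <- run_trial(specs[["mexiletine-caffeine"]], lib)$ratios$auc_ratio
  expect_gt(r_strong, r_mod)
  expect_gt(r_mod, 1)
})

test_that("qualification reports cover every pair and flag agreement", {
  # a small 2-pair panel keeps this cheap; the full 11-pair run is exercised
  # by the acceptance suite
  specs <- network_qualification_specs()[c("fluvoxamine-caffeine",
                                           "mexiletine-caffeine")]
  lib <- trial_library(solver = test_solver())
  obs <- synthetic_observed_ratios(specs, lib, cv = 0, seed = 5)
  rep <- qualify_network(specs, obs, lib)
  expect_s3_class(rep, "qualification_report")
  expect_equal(nrow(rep), 2)
  # observed == predicted -> pred/obs exactly 1, overall pass
  expect_equal(rep$pred_obs_auc, c(1, 1), tolerance = 1e-12)
  expect_true(attr(rep, "pass"))
  # a missing observed pair is recorded as prediction-only
  rep2 <- qualify_network(specs, obs[1, ], lib)
  expect_equal(rep2$status, c("compared", "prediction-only"))
  # determinism: identical inputs give identical reports
  rep3 <- qualify_network(specs, obs, lib)
  expect_identical(rep, rep3)
})

test_that("mechanism comparison ranks hypotheses by fit and keeps tie order", {
  ind <- fast_mix_individual()
  victim <- cyp_victim(cl_int = 1, enzyme = "CYP1A2")
  perp <- clamped_inhibitor(list(inhibition("CYP1A2", "tdi",
                                            k_i_tdi = 1, k_inact = 0.01)))
  sp <- trial_spec("mech", victim,
                   dosing_regimen("victim", "iv_bolus", 30, 2000),
                   perpetrator = perp,
                   perp_regimen = dosing_regimen("perp", "iv_bolus", 71, 0),
                   t_end = 3500, interval = c(2000, 3500), n_grid = 501)
  lib <- trial_library(ind, test_solver())
  truth <- run_trial(sp, lib)$ratios$auc_ratio
  variants <- list(
    competitive_only = list(inhibition("CYP1A2", "competitive", ki = 1)),
    with_tdi = list(inhibition("CYP1A2", "tdi", k_i_tdi = 1, k_inact = 0.01))
  )
  cmp <- compare_mechanisms(sp, variants, observed_auc_ratio = truth,
                            library = lib)
  expect_equal(cmp$variant[1], "with_tdi")
  expect_lt(cmp$abs_log_error[1], cmp$abs_log_error[2])
  # identical variants tie and keep their input order
  cmp2 <- compare_mechanisms(sp, list(a = variants[[1]], b = variants[[1]]),
                             observed_auc_ratio = truth, library = lib)
  expect_equal(cmp2$variant, c("a", "b"))
  expect_equal(cmp2$abs_log_error[1], cmp2$abs_log_error[2])
})
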
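# Synthetic clinical data generation and parameter recovery.

make_base_sim <- function(cl = 0.5, D = 100, t_end = 800) {
  ind <- fast_mix_individual()
  d <- mono_drug(cl)
  sim1(d, dosing_regimen("mono", "iv_bolus", D, 0), ind, t_end,
       solver = test_solver())
}

test_that("zero noise and one subject reproduce the model prediction", {
  res <- make_base_sim()
  sched <- c(15, 30, 60, 120, 240, 480)
  obs <- generate_observed(res, sched,
                           noise_model(prop_cv = 0, iiv_cv = 0, seed = 1),
                           n_subjects = 1)
  pred <- approx(res$time, res$plasma[, 1], sched)$y
  expect_equal(obs$conc, pred, tolerance = 1e-12)
  expect_false(any(obs$blq))
  expect_error(generate_observed(res, c(15, 1e5), noise_model()), "span")
})

test_that("the same seed reproduces the dataset exactly, a new seed does not", {
  res <- make_base_sim()
  sched <- c(15, 60, 240, 480)
  o1 <- generate_observed(res, sched, noise_model(seed = 42), 8)
  o2 <- generate_observed(res, sched, noise_model(seed = 42), 8)
  o3 <- generate_observed(res, sched, noise_model(seed = 43), 8)
  expect_identical(o1, o2)
  expect_false(isTRUE(all.equal(o1$conc, o3$conc)))
})

test_that("empirical residual CV matches the nominal CV at large n", {
  res <- make_base_sim()
  sched <- c(30, 120, 480)
  obs <- generate_observed(res, sched,
                           noise_model(prop_cv = 0.2, iiv_cv = 0, seed = 7),
                           n_subjects = 1000)
  for (s in sched) {
    x <- obs$conc[obs$time == s]
    cv <- sd(x) / mean(x)
    expect_gt(cv, 0.18); expect_lt(cv, 0.22)
  }
})

test_that("LLOQ censoring flags and floors low concentrations", {
  res <- make_base_sim()
  sched <- c(15, 60, 240, 480)
  big_lloq <- max(res$plasma[, 1]) * 2
  obs <- generate_observed(res, sched, noise_model(lloq = big_lloq, seed = 3),
                           5)
  expect_true(all(obs$blq))
  expect_true(all(obs$conc == big_lloq))
  # censoring never produces negative concentrations
  obs2 <- generate_observed(res, sched,
                            noise_model(prop_cv = 1, lloq = 1e-4, seed = 9),
                            50)
  expect_true(all(obs2$conc >= 0))
})

test_that("background caffeine intake elevates the pre-dose trough", {
  caff <- load_builtin_drug("caffeine")
  reg <- dosing_regimen("caffeine", "oral", "150 mg", 1440)
  sched <- c(720, 1200, 1440, 1500, 1560, 1680, 1920, 2400, 2880)
  nm <- noise_model(prop_cv = 0, iiv_cv = 0, seed = 1)
  o0 <- generate_noncompliance_caffeine(caff, reg, 0, 2880, sched, nm, 1)
  expect_equal(o0$conc[o0$time < 1440], rep(0, 2))
  ob <- generate_noncompliance_caffeine(caff, reg, 0.5, 2880, sched, nm, 1)
  expect_true(all(ob$conc[ob$time < 1440] > 0))
  expect_equal(attr(ob, "truth")$background_rate, 0.5)
  # only dietary-tagged compounds accept a background intake
  tiz <- load_builtin_drug("tizanidine")
  expect_error(generate_noncompliance_caffeine(tiz, reg, 0.1, 100, 50),
               "dietary")
})

test_that("least squares recovers parameters exactly from noiseless data", {
  ind <- fast_mix_individual()
  d <- cyp_victim(cl_int = 1.6)
  sp <- trial_spec("fit0", d, dosing_regimen("victim", "iv_bolus", 50, 0),
                   t_end = 600, n_grid = 301)
  lib <- trial_library(ind, test_solver())
  res <- sim1(d, dosing_regimen("victim", "iv_bolus", 50, 0), ind, 600,
              grid = seq(0, 600, length.out = 301), solver = test_solver())
  sched <- c(30, 60, 120, 240, 360, 480)
  obs <- generate_observed(res, sched,
                           noise_model(prop_cv = 0, iiv_cv = 0, seed = 1), 1)
  pf <- trial_predict_fn(sp, lib, obs$time)
  fit <- fit_parameters(obs, pf,
                        start = c("victim/pathway:CYP2C19/cl_int" = 0.5),
                        lower = c("victim/pathway:CYP2C19/cl_int" = 0.1),
                        upper = c("victim/pathway:CYP2C19/cl_int" = 10))
  expect_equal(unname(fit$estimates), 1.6, tolerance = 1e-3)
  expect_false(fit$non_identifiable)
})

test_that("perfectly confounded parameters are flagged non-identifiable", {
  # fu and cl_int enter victim clearance only through their product
  ind <- fast_mix_individual()
  d <- cyp_victim(cl_int = 1.6, fu = 0.5)
  sp <- trial_spec("fit2", d, dosing_regimen("victim", "iv_bolus", 50, 0),
                   t_end = 600, n_grid = 301)
  lib <- trial_library(ind, test_solver())
  res <- sim1(d, dosing_regimen("victim", "iv_bolus", 50, 0), ind, 600,
              solver = test_solver())
  sched <- c(30, 60, 120, 240, 360, 480)
  obs <- generate_observed(res, sched,
                           noise_model(prop_cv = 0.05, iiv_cv = 0, seed = 2),
                           4)
  pf <- trial_predict_fn(sp, lib, obs$time)
  fit <- fit_parameters(obs, pf,
                        start = c("victim/pathway:CYP2C19/cl_int" = 1,
                                  "victim/fu" = 0.6),
                        lower = c("victim/pathway:CYP2C19/cl_int" = 0.2,
                                  "victim/fu" = 0.1),
                        upper = c("victim/pathway:CYP2C19/cl_int" = 8,
                                  "victim/fu" = 1))
  expect_true(fit$non_identifiable ||
                any(abs(fit$correlation[upper.tri(fit$correlation)]) > 0.99,
                    na.rm = TRUE))
})

test_that("observed datasets round-trip to CSV with a truth sidecar", {
  res <- make_base_sim()
  obs <- generate_observed(res, c(30, 120, 480), noise_model(seed = 4), 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_observed_csv(obs, csv, js, truth = list(cl = 0.5))
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(obs))
  expect_equal(back$conc, obs$conc)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$true_parameters$cl, 0.5)
  expect_equal(meta$noise$seed, 4L)
})
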
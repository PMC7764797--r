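# ODE engine: rate laws, state layout, conservation, analytic reductions,
# absorption and first-pass behavior.

test_that("metabolic_rate implements the three kinetic laws", {
  lin <- pathway("CYP1A2", "linear", cl_int = 0.5)
  # cl_int * E * Cu with cl_int*E = 0.5 L/min at Cu = 1 µM -> 0.5 µmol/min
  expect_equal(metabolic_rate(lin, 1, enzyme_active = 1), 0.5)
  # competitive inhibitor at I = ki halves a linear rate
  expect_equal(metabolic_rate(lin, 1, 1, inhibitors = list(conc = 2, ki = 2)),
               0.25)
  sat <- pathway("CYP2C19", "saturable", vmax = 3, km = 0.5)
  # far above km the rate saturates at vmax*E and ignores the inhibitor
  r_hi <- metabolic_rate(sat, 5000, 2, inhibitors = list(conc = 1, ki = 1))
  expect_equal(r_hi, 3 * 2, tolerance = 1e-3)
  # far below km it is linear with slope vmax*E/km
  expect_equal(metabolic_rate(sat, 1e-4, 2), 3 * 2 / 0.5 * 1e-4,
               tolerance = 1e-3)
  uns <- pathway("UNSPECIFIC", "unspecific_hepatic", cl_apparent = 0.45)
  # apparent clearance ignores enzymes and inhibitors entirely
  expect_equal(metabolic_rate(uns, 2, NULL,
                              inhibitors = list(conc = 100, ki = 0.1)), 0.9)
  expect_error(metabolic_rate(lin, -1, 1), ">= 0")
})

test_that("enzyme turnover rate has the right fixed points", {
  expect_equal(enzyme_turnover_rate(2, 2, 0.001), 0)
  # inactivation pulls below baseline
  expect_lt(enzyme_turnover_rate(2, 2, 0.001,
                                 list(conc = 1, k_inact = 0.1, k_i_tdi = 1)), 0)
  # closed-form steady state is a zero of the rate
  E0 <- 2; kdeg <- 0.001; ki <- 0.1; KI <- 1; I <- 0.5
  Ess <- E0 * kdeg / (kdeg + ki * I / (KI + I))
  expect_equal(enzyme_turnover_rate(Ess, E0, kdeg,
                                    list(conc = I, k_inact = ki, k_i_tdi = KI)),
               0, tolerance = 1e-15)
  expect_error(enzyme_turnover_rate(-1, 1, 0.001), ">= 0")
})

test_that("state layout matches the pathway/TDI structure", {
  ind <- default_individual()
  # no TDI anywhere -> no enzyme states
  caff <- load_builtin_drug("caffeine")
  sys <- assemble(ind, list(caff),
                  list(dosing_regimen("caffeine", "iv_bolus", 10, 0)))
  expect_length(sys$enz_states, 0)
  # CYP2C19 TDI -> enzyme states in liver and gut (both express CYP2C19)
  eso <- load_builtin_drug("esomeprazole")
  sys2 <- assemble(ind, list(eso),
                   list(dosing_regimen("esomeprazole", "oral", 29, 0)))
  organs <- vapply(sys2$enz_states, `[[`, character(1), "organ")
  enz <- vapply(sys2$enz_states, `[[`, character(1), "enzyme")
  expect_setequal(paste(enz, organs), c("CYP2C19 liver", "CYP2C19 gut"))
  # co-dosing: states add, shared enzyme pools counted once
  n1 <- length(sys2$state_names)
  fluvo <- load_builtin_drug("fluvoxamine")
  sys_f <- assemble(ind, list(fluvo),
                    list(dosing_regimen("fluvoxamine", "oral", 157, 0)))
  n2 <- length(sys_f$state_names)
  sys_both <- assemble(ind, list(eso, fluvo),
                       list(dosing_regimen("esomeprazole", "oral", 29, 0),
                            dosing_regimen("fluvoxamine", "oral", 157, 0)))
  # fluvoxamine alone has no enzyme states; the combined system shares the
  # esomeprazole-induced CYP2C19 pool
  expect_length(sys_both$state_names, n1 + n2)
  expect_error(assemble(ind, list(caff),
                        list(dosing_regimen("nodrug", "iv_bolus", 1, 0))),
               "unknown drug")
  nokp <- drug("nokp", 300, fu = 0.5, kp_map = list(muscle = 2))
  expect_error(assemble(ind, list(nokp),
                        list(dosing_regimen("nokp", "iv_bolus", 1, 0))),
               "missing Kp")
})

test_that("a closed system conserves the administered amount", {
  ind <- default_individual()
  inert <- drug("inert", 300, fu = 0.5, kp_map = list(default = 2))
  res <- sim1(inert, dosing_regimen("inert", "iv_bolus", 50, 0), ind, 1000,
              solver = test_solver())
  tot <- rowSums(res$amounts[, grep("^inert", colnames(res$amounts))])
  post <- res$time > 0
  expect_lt(max(abs(tot[post] - 50)) / 50, 1e-6)
  expect_lt(res$mass_balance_error, 1e-6)
})

test_that("the fast-mixing reduction matches the one-compartment closed form", {
  ind <- fast_mix_individual()
  V <- one_compartment_volume(ind)
  cl <- 0.1; D <- 100
  d <- mono_drug(cl)
  grid <- c(seq(0, 5, by = 0.05), seq(6, 2000, length.out = 500))
  res <- sim1(d, dosing_regimen("mono", "iv_bolus", D, 0), ind, 2000, grid)
  sel <- res$time >= 30
  pred <- (D / V) * exp(-cl * res$time[sel] / V)
  expect_lt(max(abs(res$plasma[sel, 1] - pred) / pred), 1e-3)
  m <- compute_metrics(res$time, res$plasma[, 1], extrapolate = TRUE)
  expect_equal(m$auc, D / cl, tolerance = 1e-3)
  expect_lt(res$mass_balance_error, 1e-3)
})

test_that("AUC is dose-proportional for linear drugs, supra-linear only when saturable", {
  ind <- default_individual()
  d <- mono_drug(0.3)
  auc_of <- function(dd, dose) {
    res <- sim1(dd, dosing_regimen(dd$name, "iv_bolus", dose, 0), ind, 4000)
    compute_metrics(res$time, res$plasma[, 1], extrapolate = TRUE)$auc
  }
  a1 <- auc_of(d, 10); a2 <- auc_of(d, 20)
  expect_equal(a2 / a1, 2, tolerance = 1e-3)
  # saturable pathway: AUC/dose non-decreasing in dose
  dsat <- drug("sat", 300, fu = 1, kp_map = list(default = 1),
               pathways = list(pathway("CYP2C19", "saturable",
                                       vmax = 1, km = 1)))
  s1 <- auc_of(dsat, 10) / 10
  s2 <- auc_of(dsat, 100) / 100
  expect_gte(s2, s1 * (1 - 1e-6))
  expect_gt(s2, s1 * 1.05)   # saturation is actually engaged at 100 µmol
})

test_that("steady-state interval AUC obeys superposition for linear drugs", {
  ind <- default_individual()
  d <- mono_drug(0.3)
  tau <- 720; ndose <- 6
  reg <- dosing_regimen("mono", "iv_bolus", 30, seq(0, by = tau,
                                                    length.out = ndose))
  res <- sim1(d, reg, ind, ndose * tau,
              grid = seq(0, ndose * tau, by = 2))
  auc_ss <- compute_metrics(res$time, res$plasma[, 1],
                            interval = c((ndose - 1) * tau, ndose * tau))$auc
  res1 <- sim1(d, dosing_regimen("mono", "iv_bolus", 30, 0), ind, 6000,
               grid = seq(0, 6000, by = 2))
  auc_inf <- compute_metrics(res1$time, res1$plasma[, 1],
                             extrapolate = TRUE)$auc
  expect_equal(auc_ss, auc_inf, tolerance = 0.01)
})

test_that("TDI autoinhibition accumulates beyond linear superposition", {
  ind <- default_individual()
  moclo <- load_builtin_drug("moclobemide")
  tau <- 1440; ndose <- 5
  reg <- dosing_regimen("moclobemide", "oral", "300 mg",
                        seq(0, by = tau, length.out = ndose))
  res <- sim1(moclo, reg, ind, ndose * tau, solver = test_solver())
  auc_ss <- compute_metrics(res$time, res$plasma[, 1],
                            interval = c((ndose - 1) * tau, ndose * tau))$auc
  res1 <- sim1(moclo, dosing_regimen("moclobemide", "oral", "300 mg", 0),
               ind, 4 * tau, solver = test_solver())
  auc_inf <- compute_metrics(res1$time, res1$plasma[, 1],
                             extrapolate = TRUE)$auc
  expect_gt(auc_ss / auc_inf, 1.02)
  # the active CYP2C19 fraction is genuinely depressed at steady state
  expect_lt(min(res$enzyme[, "CYP2C19|liver"]), 0.95)
})

test_that("doubling the output grid changes AUC and Cmax by < 0.1%", {
  ind <- default_individual()
  d <- load_builtin_drug("caffeine")
  reg <- dosing_regimen("caffeine", "oral", "150 mg", 0)
  r1 <- sim1(d, reg, ind, 1440, grid = seq(0, 1440, length.out = 481))
  r2 <- sim1(d, reg, ind, 1440, grid = seq(0, 1440, length.out = 961))
  m1 <- compute_metrics(r1$time, r1$plasma[, 1])
  m2 <- compute_metrics(r2$time, r2$plasma[, 1])
  expect_equal(m1$auc, m2$auc, tolerance = 1e-3)
  expect_equal(m1$cmax, m2$cmax, tolerance = 1e-3)
})

test_that("absorption handles f_abs, the Weibull identity and the fast-ka limit", {
  ind <- default_individual()
  base <- load_builtin_drug("caffeine")   # no gut enzymes
  # fraction 1 - f_abs never reaches the portal vein
  d60 <- base; d60$absorption$f_abs <- 0.6
  r_full <- sim1(base, dosing_regimen("caffeine", "oral", 100, 0), ind, 2880,
                 solver = test_solver())
  r_part <- sim1(d60, dosing_regimen("caffeine", "oral", 100, 0), ind, 2880,
                 solver = test_solver())
  unab <- unname(r_part$amounts[nrow(r_part$amounts), "caffeine|unabsorbed"])
  expect_equal(unab, 40, tolerance = 1e-3)
  auc_f <- compute_metrics(r_full$time, r_full$plasma[, 1],
                           extrapolate = TRUE)$auc
  auc_p <- compute_metrics(r_part$time, r_part$plasma[, 1],
                           extrapolate = TRUE)$auc
  expect_equal(auc_p / auc_f, 0.6, tolerance = 1e-3)

  # Weibull release with shape 1 == first-order release at rate 1/scale:
  # release-limited absorption with scale 30 matches plain ka = 1/30
  dw <- base
  dw$absorption <- list(ka = 10, f_abs = 1, weibull_scale = 30,
                        weibull_shape = 1)
  df <- base; df$absorption <- list(ka = 1 / 30, f_abs = 1)
  rw <- sim1(dw, dosing_regimen("caffeine", "oral", 100, 0), ind, 1440,
             solver = test_solver())
  rf <- sim1(df, dosing_regimen("caffeine", "oral", 100, 0), ind, 1440,
             solver = test_solver())
  mw <- compute_metrics(rw$time, rw$plasma[, 1])
  mf <- compute_metrics(rf$time, rf$plasma[, 1])
  expect_equal(mw$auc, mf$auc, tolerance = 0.02)
  expect_equal(mw$cmax, mf$cmax, tolerance = 0.03)

  # ka -> infinity limit: the profile stops depending on ka
  dk1 <- base; dk1$absorption$ka <- 10
  dk2 <- base; dk2$absorption$ka <- 50
  rk1 <- sim1(dk1, dosing_regimen("caffeine", "oral", 100, 0), ind, 1440,
              solver = test_solver())
  rk2 <- sim1(dk2, dosing_regimen("caffeine", "oral", 100, 0), ind, 1440,
              solver = test_solver())
  a1 <- compute_metrics(rk1$time, rk1$plasma[, 1])$auc
  a2 <- compute_metrics(rk2$time, rk2$plasma[, 1])$auc
  expect_equal(a1, a2, tolerance = 0.01)
  expect_error(sim1(drug("noab", 300, fu = 0.5),
                    dosing_regimen("noab", "oral", 10, 0), ind, 100),
               "absorption")
})

test_that("lowering gut CYP2C19 raises oral bioavailability monotonically", {
  ind <- default_individual()
  rome <- load_builtin_drug("r-omeprazole")
  # exaggerate gut expression so first-pass gut extraction is visible
  ind$expression$CYP2C19[["gut"]] <- 0.2
  ind <- validate_individual(ind)
  auc_at <- function(f) {
    i2 <- scale_gut_expression(ind, "CYP2C19", f)
    r <- sim1(rome, dosing_regimen("r-omeprazole", "oral", 29, 0), i2, 1440,
              solver = test_solver())
    compute_metrics(r$time, r$plasma[, 1], extrapolate = TRUE)$auc
  }
  a0 <- auc_at(0); a05 <- auc_at(0.5); a1 <- auc_at(1)
  expect_gt(a0, a05)
  expect_gt(a05, a1)
})

test_that("simulation rejects an end time before the last dose", {
  ind <- default_individual()
  d <- mono_drug(0.1)
  sys <- assemble(ind, list(d),
                  list(dosing_regimen("mono", "iv_bolus", 10, c(0, 500))))
  expect_error(simulate_pbpk(sys, 400), "cover")
})
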
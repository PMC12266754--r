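# Synthetic-cohort generators: determinism, closed-form structure, recovery.

test_that("generators are deterministic under a fixed seed and NaN-free", {
  cfg <- small_cfg(n = 100, seed = 5)
  e1 <- gen_expression(cfg); e2 <- gen_expression(cfg)
  expect_identical(unclass(e1), unclass(e2))
  expect_true(all(is.finite(e1)))
  c1 <- simulate_cohort(cfg); c2 <- simulate_cohort(cfg)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$proteomics, c2$proteomics)
  expect_true(all(is.finite(as.matrix(c1$phenotypes[, -(1:3)]))))
  expect_true(all(is.finite(c1$proteomics)))
  # different seeds differ
  e3 <- gen_expression(small_cfg(n = 100, seed = 6))
  expect_false(identical(unclass(e1), unclass(e3)))
  # substreams: the survival draw does not perturb the expression draw
  expect_identical(unclass(c1$expression), unclass(e1))
})

test_that("within-set gene correlation matches the factor-model closed form", {
  specs <- data.frame(name = c("SAS-1", "MAS-1"), n_genes = 20L,
                      rho = c(0, 0.5), cluster = c("SAS", "MAS"),
                      loading = 1, frac_neg = 0, role = "IR-metric")
  # rho = 0: mean |pairwise correlation| below the 3-sigma null bound
  cfg0 <- sim_config(n_subjects = 2000, seed = 91, signature_specs = specs,
                     n_noise_genes = 0)
  ex <- gen_expression(cfg0)
  sig <- attr(ex, "signatures")
  cc0 <- cor(t(ex[sig[["SAS-1"]]$genes, ]))
  expect_lt(mean(abs(cc0[upper.tri(cc0)])), 0.05)
  # rho = 0.5 at n = 5000: empirical mean within-set correlation in [.45,.55]
  cfg5 <- sim_config(n_subjects = 5000, seed = 92, signature_specs = specs,
                     n_noise_genes = 0)
  ex5 <- gen_expression(cfg5)
  cc5 <- cor(t(ex5[attr(ex5, "signatures")[["MAS-1"]]$genes, ]))
  m <- mean(cc5[upper.tri(cc5)])
  expect_gt(m, 0.45); expect_lt(m, 0.55)
})

test_that("oriented members anti-correlate and the scorer recovers the latent", {
  cfg <- small_cfg(n = 1000, seed = 93)
  ex <- gen_expression(cfg)
  sig <- attr(ex, "signatures")[["EL-down"]]  # has frac_neg = 0.3
  neg <- sig$genes[sig$orientation == -1L][1]
  pos <- sig$genes[sig$orientation == 1L][1]
  expect_lt(cor(ex[neg, ], ex[pos, ]), 0)
  z <- suppressWarnings(zscore_genes(ex))
  sc <- score_signature(z, sig)
  expect_gt(cor(sc, attr(ex, "truth")[["EL-down"]]), 0.6)
})

test_that("profile prevalences are recovered within 0.03 at n = 5000", {
  coh <- simulate_cohort(sim_config(n_subjects = 5000, seed = 94))
  prev <- prop.table(table(coh$profile))
  target <- coh$config$profile_prevalences[names(prev)]
  expect_true(all(abs(prev - target) < 0.03))
})

test_that("gen_survival matches the exponential closed form with no effects", {
  cfg <- sim_config(n_subjects = 10000, seed = 95, beta_age = 0,
                    beta_group = c("H-L" = 0, "H-H" = 0, "L-L" = 0,
                                   "L-H" = 0),
                    baseline_rate = 0.05, censor_horizon = 9)
  sv <- gen_survival(cfg, rep(50, 10000), rep("H-L", 10000))
  # event fraction = 1 - exp(-lambda * horizon) = 0.3624; 3 sigma ~ 0.015
  expect_lt(abs(mean(sv$event) - (1 - exp(-0.45))), 0.015)
  expect_true(all(sv$time > 0 & sv$time <= 9))
  # calibrated rate hits the target event fraction
  cfg2 <- sim_config(n_subjects = 10000, seed = 95)
  ages <- with_seed(1, runif(10000, 40, 92))
  sv2 <- gen_survival(cfg2, ages, rep("H-L", 10000))
  expect_lt(abs(mean(sv2$event) - 0.2), 0.02)
  # vanishing horizon: everything censored
  cfg3 <- sim_config(n_subjects = 100, seed = 95, baseline_rate = 0.05,
                     censor_horizon = 1e-9)
  sv3 <- gen_survival(cfg3, rep(50, 100), rep("H-L", 100))
  expect_equal(sum(sv3$event), 0)
  expect_error(gen_survival(cfg2, ages, rep("unknown", 10000)), "beta_group")
})

test_that("the Gompertz baseline calibrates and censors like the exponential", {
  cfg <- sim_config(n_subjects = 5000, seed = 96,
                    baseline_hazard = "gompertz", gompertz_shape = 0.15)
  ages <- with_seed(2, runif(5000, 40, 92))
  sv <- gen_survival(cfg, ages, rep("H-L", 5000))
  expect_lt(abs(mean(sv$event) - 0.2), 0.025)
  expect_true(all(sv$time > 0 & sv$time <= 9))
})

test_that("gen_longitudinal honours the trajectory grammar", {
  cfg_all_pres <- small_cfg(n = 50, seed = 97,
                            trajectory_mix = c(preserver = 1,
                                               reconstituter = 0,
                                               degrader = 0))
  lng <- gen_longitudinal(cfg_all_pres)
  expect_true(all(lng$profile == "H-L"))
  cfg_mix <- small_cfg(n = 400, seed = 98)
  lng2 <- gen_longitudinal(cfg_mix)
  truth <- attr(lng2, "truth")
  wide <- split(lng2, lng2$subject)
  for (s in truth$subject[truth$class == "degrader"]) {
    prof <- wide[[s]]$profile[order(wide[[s]]$timepoint)]
    expect_false(as.character(prof[length(prof)]) == "H-L")
    expect_equal(as.character(prof[1]), "H-L")  # baseline always optimal
  }
  expect_error(gen_longitudinal(sim_config(timepoints = c("T0", "T1"))),
               "3 timepoints")
})

test_that("five-timepoint sequences keep reconstituters recoverable", {
  cfg <- small_cfg(n = 300, seed = 99,
                   timepoints = c("T0", "T1", "T2", "T3", "T6"))
  lng <- gen_longitudinal(cfg)
  lab <- classify_trajectories(lng)
  truth <- attr(lng, "truth")
  merged <- merge(lab, truth, by = "subject")
  expect_equal(merged$label, merged$class)
})

test_that("gen_proteomics plants the requested association structure", {
  cfg <- small_cfg(n = 200, seed = 101)
  sas <- setNames(with_seed(1, rnorm(200)), paste0("s", 1:200))
  mas <- setNames(with_seed(2, rnorm(200)), paste0("s", 1:200))
  prot <- gen_proteomics(cfg, sas, mas)
  truth <- attr(prot, "truth")
  expect_equal(ncol(prot), cfg$proteomic_spec$n_proteins)
  expect_equal(sum(truth$assoc == "both"), cfg$proteomic_spec$n_shared)
  # a SAS-planted protein correlates with sas, a none protein with neither
  p_sas <- truth$protein[truth$assoc == "SAS"][1]
  expect_gt(cor(prot[, p_sas], sas), 0.4)
  p_none <- truth$protein[truth$assoc == "none"][1]
  expect_lt(abs(cor(prot[, p_none], sas)), 0.2)
  expect_identical(prot, gen_proteomics(cfg, sas, mas))
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(profile_prevalences = c("H-L" = 0.5, "H-H" = 0.3,
                                                  "L-L" = 0.1, "L-H" = 0.1)),
               "0.5")
  expect_error(sim_config(trajectory_mix = c(preserver = 0.5,
                                             reconstituter = 0.5,
                                             degrader = 0.5)), "sum to 1")
  expect_error(sim_config(censor_horizon = 0), "censor_horizon")
  specs <- default_signature_specs(); specs$rho[1] <- 1
  expect_error(sim_config(signature_specs = specs), "rho")
  specs2 <- default_signature_specs(); specs2$n_genes[1] <- 0
  expect_error(sim_config(signature_specs = specs2), "n_genes")
  ps <- list(n_proteins = 10L, n_true_sas = 8L, n_true_mas = 8L,
             n_shared = 0L, effect = 1, noise_sd = 1)
  expect_error(sim_config(proteomic_spec = ps), "exceed")
})
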
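# Replicated parameter-recovery simulations for the survival machinery.

#' Simulate-and-refit recovery of planted hazard effects
#'
#' Repeatedly simulates a two-group cohort (optimal vs degraded IR profile)
#' with a planted per-year log-hazard slope and group offset, fits a
#' proportional-hazards model on age and group per replicate, and returns
#' the per-replicate hazard ratio, equivalence age and survival gap. This is
#' the engine behind the headline checks: with the defaults
#' (`beta_offset = 2.273`, `beta_age = 0.1467`) the mean recovered HR is ~9.7
#' and the mean gap ~15.5 years at reference age 40.
#'
#' @param n_reps number of replicate cohorts.
#' @param n subjects per cohort.
#' @param age_range uniform baseline-age range (years).
#' @param frac_exposed fraction of subjects in the exposed group.
#' @param beta_age per-year log-hazard slope.
#' @param beta_offset log-hazard offset of the exposed group.
#' @param event_frac target marginal event fraction.
#' @param censor_horizon administrative censoring time (years).
#' @param ref_age reference age for the equivalence statistic.
#' @param seed global seed; each replicate uses a deterministic substream.
#' @return data.frame, one row per replicate: `rep`, `hr`, `beta_group`,
#'   `beta_age`, `gap`, `equivalence_age`, `events`.
#' @export
simulate_hazard_recovery <- function(n_reps = 100, n = 5000,
                                     age_range = c(40, 92),
                                     frac_exposed = 0.1,
                                     beta_age = 0.1467,
                                     beta_offset = 2.273,
                                     event_frac = 0.2, censor_horizon = 9,
                                     ref_age = 40, seed = 1) {
  out <- vector("list", n_reps)
  n_exp <- round(n * frac_exposed)
  groups <- rep(c("L-H", "H-L"), c(n_exp, n - n_exp))
  for (i in seq_len(n_reps)) {
    rs <- substream_seed(seed, sprintf("hazrec-%d", i))
    cfg <- sim_config(n_subjects = n, seed = rs, age_range = age_range,
                      beta_age = beta_age,
                      beta_group = c("H-L" = 0, "H-H" = 0, "L-L" = 0,
                                     "L-H" = beta_offset),
                      age_ref = ref_age, event_frac = event_frac,
                      censor_horizon = censor_horizon)
    ages <- with_seed(substream_seed(rs, "ages"),
                      stats::runif(n, age_range[1], age_range[2]))
    sv <- gen_survival(cfg, ages, groups)
    d <- data.frame(time = sv$time, event = sv$event, age = ages,
                    exposed = as.integer(groups == "L-H"))
    fit <- fit_ph(d, c("age", "exposed"))
    eq <- equivalence_age(fit, "exposed", "age", ref_age = ref_age)
    out[[i]] <- data.frame(
      rep = i, hr = unname(exp(fit$coefficients[["exposed"]])),
      beta_group = unname(fit$coefficients[["exposed"]]),
      beta_age = unname(fit$coefficients[["age"]]),
      gap = eq$gap, equivalence_age = eq$equivalence_age,
      events = fit$events)
  }
  do.call(rbind, out)
}
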
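# Simulation configuration: the stated world every generator draws from.

#' Default signature specifications for the simulator
#'
#' Two IR metrics (SAS-1, MAS-1) and the six salutogenesis readouts, each a
#' correlated gene block: member genes share a latent factor with loading
#' `sqrt(rho)` plus independent noise, so the within-set pairwise
#' correlation equals `rho` in closed form. `cluster` ties a signature's
#' latent to the survival-associated (SAS) or mortality-associated (MAS)
#' factor; `loading` is the share of latent variance drawn from the cluster
#' factor (the IR metrics load fully, readouts partially). `frac_neg` is the
#' fraction of members oriented -1.
#'
#' @return data.frame of signature specs.
#' @export
default_signature_specs <- function() {
  data.frame(
    name = c("SAS-1", "MAS-1", "IMM-AGE", "EL-down", "tTCH-high",
             "AgeIL6-up", "InflammAge-up", "SenMayo"),
    n_genes = c(20L, 20L, 10L, 10L, 10L, 10L, 10L, 10L),
    rho = 0.3,
    cluster = c("SAS", "MAS", "SAS", "SAS", "SAS", "MAS", "MAS", "MAS"),
    loading = c(1, 1, rep(0.6, 6)),
    frac_neg = c(0, 0, 0, 0.3, 0, 0, 0, 0),
    role = c("IR-metric", "IR-metric",
             "pos-salutogenesis", "pos-salutogenesis", "pos-salutogenesis",
             "neg-salutogenesis", "neg-salutogenesis", "neg-salutogenesis"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort world; defaults state the
#' conditions the analysis assumes (see the methods vignette for the
#' rationale behind each value). Profiles arise from median splits, so their
#' marginals are fixed at 1/2: `profile_prevalences` must satisfy
#' `P(H-L)+P(H-H) = 0.5` (and hence `P(H-L)=P(L-H)`, `P(H-H)=P(L-L)`).
#'
#' @param n_subjects cohort size.
#' @param seed global integer seed; each generator uses a deterministic
#'   substream derived from it.
#' @param age_range baseline age range in years (uniform draw).
#' @param sex_ratio fraction female.
#' @param signature_specs data.frame as [default_signature_specs()].
#' @param n_noise_genes unstructured background genes.
#' @param tcf7_coupling target log-odds of SAS-1-high per unit TCF7 z
#'   (mapped to a latent Gaussian correlation; see vignette).
#' @param profile_prevalences named fractions over `H-L, H-H, L-L, L-H`.
#' @param age_coupling loading of age on the cluster factors (SAS falls,
#'   MAS rises with age).
#' @param beta_age per-year log-hazard slope.
#' @param beta_group named log-hazard offsets per IR profile.
#' @param age_ref age at which the age term is centred (years).
#' @param censor_horizon administrative censoring time (years).
#' @param event_frac target marginal event fraction before the horizon; the
#'   baseline rate is calibrated to it unless `baseline_rate` is given.
#' @param baseline_rate optional fixed baseline hazard rate (events/year).
#' @param baseline_hazard `"exponential"` (default) or `"gompertz"`.
#' @param gompertz_shape log-hazard increase per year of follow-up time
#'   (used only for the Gompertz baseline).
#' @param trajectory_mix named fractions over
#'   `preserver, reconstituter, degrader`.
#' @param timepoints ordered timepoint labels (>= 3) for longitudinal draws.
#' @param offprofile_weights sampling weights for non-optimal profiles in
#'   longitudinal draws.
#' @param grade_prevalences named fractions over the eight IHG grades.
#' @param ihg IHG thresholds used to truncate the count sampler.
#' @param proteomic_spec list: `n_proteins`, `n_true_sas`, `n_true_mas`,
#'   `n_shared` (both-associated, additional to the exclusive counts),
#'   `effect` (abundance units per score z), `noise_sd`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(
    n_subjects = 1000L,
    seed = 1L,
    age_range = c(40, 92),
    sex_ratio = 0.55,
    signature_specs = default_signature_specs(),
    n_noise_genes = 200L,
    tcf7_coupling = 1.0,
    profile_prevalences = c("H-L" = 0.35, "H-H" = 0.15,
                            "L-L" = 0.15, "L-H" = 0.35),
    age_coupling = 0.3,
    beta_age = 0.1467,
    beta_group = c("H-L" = 0, "H-H" = 0.8, "L-L" = 0.8, "L-H" = 2.273),
    age_ref = 40,
    censor_horizon = 9,
    event_frac = 0.2,
    baseline_rate = NULL,
    baseline_hazard = c("exponential", "gompertz"),
    gompertz_shape = 0.1,
    trajectory_mix = c(preserver = 0.35, reconstituter = 0.26,
                       degrader = 0.39),
    timepoints = c("T0", "T1", "T6"),
    offprofile_weights = c("H-H" = 0.25, "L-L" = 0.25, "L-H" = 0.5),
    grade_prevalences = c(I = 0.60, IIa = 0.15, IIb = 0.07, IIc = 0.002,
                          III = 0.08, IVa = 0.06, IVb = 0.036, IVc = 0.002),
    ihg = ihg_thresholds(),
    proteomic_spec = list(n_proteins = 1304L, n_true_sas = 349L,
                          n_true_mas = 274L, n_shared = 25L,
                          effect = 0.8, noise_sd = 1)) {
  baseline_hazard <- match.arg(baseline_hazard)
  stopifnot(n_subjects >= 1, length(age_range) == 2L,
            age_range[1] < age_range[2])
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0,1]")
  specs <- as.data.frame(signature_specs)
  if (any(specs$n_genes < 1L))
    stop("every signature needs n_genes >= 1", call. = FALSE)
  if (any(specs$rho < 0 | specs$rho >= 1))
    stop("within-set correlation rho must lie in [0, 1)", call. = FALSE)
  assert_prob_vector(profile_prevalences, "profile_prevalences")
  if (!setequal(names(profile_prevalences), ir_profile_levels()))
    stop("profile_prevalences must be named over ",
         paste(ir_profile_levels(), collapse = ", "), call. = FALSE)
  marg <- profile_prevalences[["H-L"]] + profile_prevalences[["H-H"]]
  if (abs(marg - 0.5) > 1e-8)
    stop("median splits force P(H-L)+P(H-H) = 0.5; got ", marg, call. = FALSE)
  assert_prob_vector(trajectory_mix, "trajectory_mix")
  assert_prob_vector(grade_prevalences, "grade_prevalences")
  if (!setequal(names(grade_prevalences), ihg_levels()))
    stop("grade_prevalences must cover all IHG grades", call. = FALSE)
  if (censor_horizon <= 0) stop("censor_horizon must be > 0", call. = FALSE)
  if (!is.null(baseline_rate) && baseline_rate <= 0)
    stop("baseline_rate must be positive", call. = FALSE)
  if (event_frac <= 0 || event_frac >= 1)
    stop("event_frac must be in (0,1)", call. = FALSE)
  if (!all(is.finite(c(beta_age, beta_group))))
    stop("beta_age and beta_group must be finite", call. = FALSE)
  if (length(timepoints) < 3L)
    stop("need at least 3 timepoints (baseline, intermediate, final)",
         call. = FALSE)
  ps <- proteomic_spec
  if (ps$n_true_sas + ps$n_true_mas + ps$n_shared > ps$n_proteins)
    stop("planted proteins exceed n_proteins", call. = FALSE)
  if (abs(age_coupling) >= 1) stop("age_coupling must be in (-1,1)")
  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    age_range = age_range, sex_ratio = sex_ratio,
    signature_specs = specs, n_noise_genes = as.integer(n_noise_genes),
    tcf7_coupling = tcf7_coupling,
    profile_prevalences = profile_prevalences[ir_profile_levels()],
    age_coupling = age_coupling,
    beta_age = beta_age, beta_group = beta_group, age_ref = age_ref,
    censor_horizon = censor_horizon, event_frac = event_frac,
    baseline_rate = baseline_rate, baseline_hazard = baseline_hazard,
    gompertz_shape = gompertz_shape,
    trajectory_mix = trajectory_mix,
    timepoints = timepoints, offprofile_weights = offprofile_weights,
    grade_prevalences = grade_prevalences[ihg_levels()],
    ihg = ihg, proteomic_spec = ps),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> n=%d seed=%d ages %g-%g; %d signatures; %s\n",
              x$n_subjects, x$seed, x$age_range[1], x$age_range[2],
              nrow(x$signature_specs), x$baseline_hazard))
  invisible(x)
}
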
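# Synthetic-cohort generators. All randomness flows through deterministic
# substreams of config$seed, so any subset of generators reruns identically.

#' Baseline ages and sex
#'
#' @param config a [sim_config()].
#' @return data.frame: `subject`, `age` (uniform over `age_range`), `sex`
#'   (`"F"`/`"M"` at `sex_ratio`).
#' @export
gen_phenotype_base <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  with_seed(substream_seed(config$seed, "phenotype"), {
    data.frame(
      subject = sprintf("S%05d", seq_len(n)),
      age = stats::runif(n, config$age_range[1], config$age_range[2]),
      sex = ifelse(stats::runif(n) < config$sex_ratio, "F", "M"))
  })
}

# Map a target logistic (log-odds per z) slope for P(high | t) to the latent
# Gaussian correlation r between the TCF7 z and the SAS-1 latent: for
# bivariate normals P(S > 0 | t) = pnorm(c*t) with c = r/sqrt(1-r^2), and
# the probit slope c corresponds to a logit slope of ~1.7c.
tcf7_corr_from_coupling <- function(b) {
  c_probit <- b / 1.7
  c_probit / sqrt(1 + c_probit^2)
}

#' Generate a synthetic expression matrix with planted signature structure
#'
#' Factor model: each signature's member genes share a latent with loading
#' `sqrt(rho)` plus independent unit noise, so within-set pairwise
#' correlation is exactly `rho` (sign-flipped for -1-oriented members).
#' Signature latents in the SAS cluster draw on a common survival factor and
#' MAS-cluster latents on a mortality factor; the two factors are correlated
#' so that median splits of the SAS-1/MAS-1 latents reproduce
#' `profile_prevalences` (Gaussian quadrant formula), and both factors drift
#' with age at `age_coupling` (SAS down, MAS up). A TCF7 gene is coupled to
#' the SAS-1 latent at the configured log-odds slope, and `n_noise_genes`
#' unstructured genes are appended. Genes carry log-scale baseline offsets,
#' so z-scoring is a real step downstream.
#'
#' @param config a [sim_config()].
#' @param ages,sex optional vectors from [gen_phenotype_base()] (drawn
#'   internally when omitted).
#' @return genes x samples matrix with attributes `signatures` (list of
#'   [gene_signature()] including the TCF7 single-gene marker) and `truth`
#'   (data.frame of per-sample latents and the planted profile).
#' @export
gen_expression <- function(config, ages = NULL, sex = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  base <- NULL
  if (is.null(ages)) {
    base <- gen_phenotype_base(config)
    ages <- base$age
  }
  specs <- config$signature_specs
  p_hl <- config$profile_prevalences[["H-L"]]
  rho_target <- sin(2 * pi * (0.25 - p_hl))  # quadrant formula inverse
  a <- config$age_coupling
  rho_core <- (rho_target - (-a) * a) / (1 - a^2)
  if (abs(rho_core) >= 1)
    stop("profile prevalences incompatible with age_coupling", call. = FALSE)

  with_seed(substream_seed(config$seed, "expression"), {
    z_age <- as.numeric(scale(ages))
    g_s <- stats::rnorm(n)
    g_m <- rho_core * g_s + sqrt(1 - rho_core^2) * stats::rnorm(n)
    f_sas <- -a * z_age + sqrt(1 - a^2) * g_s
    f_mas <-  a * z_age + sqrt(1 - a^2) * g_m
    cluster_factor <- list(SAS = f_sas, MAS = f_mas)

    sample_ids <- sprintf("S%05d", seq_len(n))
    blocks <- list(); sigs <- list()
    latents <- matrix(NA_real_, n, nrow(specs),
                      dimnames = list(sample_ids, specs$name))
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      w <- sp$loading
      lat <- if (sp$cluster %in% names(cluster_factor))
        sqrt(w) * cluster_factor[[sp$cluster]] +
          sqrt(1 - w) * stats::rnorm(n)
      else stats::rnorm(n)
      latents[, i] <- lat
      n_neg <- round(sp$frac_neg * sp$n_genes)
      orient <- rep(c(-1L, 1L), c(n_neg, sp$n_genes - n_neg))
      gene_ids <- sprintf("%s_G%03d", gsub("[^A-Za-z0-9]", "", sp$name),
                          seq_len(sp$n_genes))
      mu <- stats::rnorm(sp$n_genes, mean = 7, sd = 1.5)
      eps <- matrix(stats::rnorm(sp$n_genes * n), sp$n_genes, n)
      block <- orient * (sqrt(sp$rho) * rep(1, sp$n_genes) %o% lat) +
        sqrt(1 - sp$rho) * eps + mu
      rownames(block) <- gene_ids
      blocks[[i]] <- block
      sigs[[sp$name]] <- gene_signature(sp$name, gene_ids, orient,
                                        role = sp$role)
    }
    r_t <- tcf7_corr_from_coupling(config$tcf7_coupling)
    tcf7_z <- r_t * latents[, "SAS-1"] + sqrt(1 - r_t^2) * stats::rnorm(n)
    tcf7_row <- matrix(tcf7_z + 8, 1, n, dimnames = list("TCF7", NULL))
    sigs[["TCF7"]] <- gene_signature("TCF7", "TCF7", role = "single-gene")
    noise <- NULL
    if (config$n_noise_genes > 0) {
      mu <- stats::rnorm(config$n_noise_genes, 7, 1.5)
      noise <- matrix(stats::rnorm(config$n_noise_genes * n), ncol = n) + mu
      rownames(noise) <- sprintf("NOISE_G%04d", seq_len(config$n_noise_genes))
    }
    expr <- do.call(rbind, c(blocks, list(tcf7_row), list(noise)))
    colnames(expr) <- sample_ids

    truth <- data.frame(subject = sample_ids, age = ages,
                        latents, tcf7_z = tcf7_z, check.names = FALSE)
    truth$true_profile <- make_profile(
      factor(ifelse(latents[, "SAS-1"] > 0, "H", "L"), levels = c("H", "L")),
      factor(ifelse(latents[, "MAS-1"] > 0, "H", "L"), levels = c("H", "L")))
    structure(expr, signatures = sigs, truth = truth)
  })
}

# Solve for the baseline rate giving the target marginal event fraction
# under administrative censoring, for either baseline hazard.
calibrate_baseline_rate <- function(config, eta) {
  H <- config$censor_horizon
  frac <- function(lambda) {
    if (config$baseline_hazard == "exponential") {
      mean(1 - exp(-lambda * exp(eta) * H))
    } else {
      g <- config$gompertz_shape
      mean(1 - exp(-lambda * exp(eta) / g * (exp(g * H) - 1)))
    }
  }
  f <- function(loglam) frac(exp(loglam)) - config$event_frac
  exp(stats::uniroot(f, c(-25, 10), tol = 1e-10)$root)
}

#' Generate survival times with planted age and group effects
#'
#' Event times follow the configured baseline hazard scaled by
#' `exp(beta_age * (age - age_ref) + beta_group[group])`, with
#' administrative censoring at `censor_horizon`. Unless `baseline_rate` is
#' fixed in the config, it is calibrated deterministically so the marginal
#' event fraction matches `event_frac`.
#'
#' @param config a [sim_config()].
#' @param ages numeric baseline ages.
#' @param groups character/factor of group labels; must all have an entry in
#'   `config$beta_group`.
#' @return data.frame: `time` (> 0), `event` (0/1); attributes
#'   `baseline_rate` and `linear_predictor`.
#' @export
gen_survival <- function(config, ages, groups) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(ages)
  if (length(groups) != n) stop("ages/groups length mismatch", call. = FALSE)
  groups <- as.character(groups)
  unknown <- setdiff(unique(groups), names(config$beta_group))
  if (length(unknown))
    stop("no beta_group entry for group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  eta <- config$beta_age * (ages - config$age_ref) +
    unname(config$beta_group[groups])
  assert_finite(eta, "log-hazard linear predictor")
  lambda0 <- config$baseline_rate
  if (is.null(lambda0)) lambda0 <- calibrate_baseline_rate(config, eta)
  if (lambda0 <= 0) stop("baseline rate must be positive", call. = FALSE)
  with_seed(substream_seed(config$seed, "survival"), {
    if (config$baseline_hazard == "exponential") {
      t_event <- stats::rexp(n, rate = lambda0 * exp(eta))
    } else {
      g <- config$gompertz_shape
      u <- stats::runif(n)
      t_event <- log1p(-g * log(u) / (lambda0 * exp(eta))) / g
    }
    H <- config$censor_horizon
    event <- as.integer(t_event <= H)
    time <- pmin(t_event, H)
    time[time <= 0] <- .Machine$double.eps  # guard against underflow
    structure(data.frame(time = time, event = event),
              baseline_rate = lambda0, linear_predictor = eta)
  })
}

#' Generate longitudinal IR-profile sequences
#'
#' Draws a trajectory class per subject from `trajectory_mix` and emits the
#' corresponding ordered profile sequence over `config$timepoints`: baseline
#' is always optimal (`H-L`); preservers stay `H-L` throughout;
#' reconstituters depart from `H-L` at one or more intermediate timepoints
#' but regain it at the final one; degraders end non-`H-L`. Non-optimal
#' states are drawn from `offprofile_weights`.
#'
#' @param config a [sim_config()].
#' @return long data.frame `subject`, `timepoint`, `profile` with attribute
#'   `truth` (data.frame `subject`, `class`).
#' @export
gen_longitudinal <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tps <- config$timepoints
  if (length(tps) < 3L) stop("need >= 3 timepoints", call. = FALSE)
  n <- config$n_subjects
  k <- length(tps) - 2L  # intermediates
  offp <- config$offprofile_weights
  with_seed(substream_seed(config$seed, "longitudinal"), {
    classes <- sample(names(config$trajectory_mix), n, replace = TRUE,
                      prob = config$trajectory_mix)
    draw_off <- function(m) sample(names(offp), m, replace = TRUE, prob = offp)
    seqs <- lapply(classes, function(cl) {
      mid <- rep("H-L", k)
      if (cl != "preserver") {
        hit <- stats::runif(k) < 0.8
        hit[1] <- TRUE  # guarantee an observed departure
        mid[hit] <- draw_off(sum(hit))
      }
      final <- if (cl == "degrader") draw_off(1L) else "H-L"
      c("H-L", mid, final)
    })
    subj <- sprintf("S%05d", seq_len(n))
    out <- data.frame(
      subject = rep(subj, each = length(tps)),
      timepoint = factor(rep(tps, n), levels = tps),
      profile = factor(unlist(seqs), levels = ir_profile_levels()))
    structure(out, truth = data.frame(subject = subj, class = classes))
  })
}

#' Generate CD4/CD8 T-cell counts targeting IHG grade prevalences
#'
#' Draws a target grade per subject from `grade_prevalences`, then samples
#' log-normal CD4 counts and CD4:CD8 ratios from per-grade proposals,
#' rejecting draws that leave the grade's region of the
#' (ratio cutoff, CD4 band) decision space.
#'
#' @param config a [sim_config()].
#' @return data.frame `cd4`, `cd8` (cells/uL, positive) with attribute
#'   `truth` (data.frame `subject`, `grade`).
#' @export
gen_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  thr <- config$ihg
  b <- thr$subgrade_bands
  # per-grade (cd4 location, cd4 range, ratio location, ratio range)
  props <- list(
    I   = list(cd4 = c(950, thr$cd4_high, Inf), ratio = c(1.7, thr$ratio_cutoff, Inf)),
    IIa = list(cd4 = c(640, b[1], thr$cd4_high), ratio = c(1.5, thr$ratio_cutoff, Inf)),
    IIb = list(cd4 = c(340, b[2], b[1]), ratio = c(1.4, thr$ratio_cutoff, Inf)),
    IIc = list(cd4 = c(120, 0, b[2]), ratio = c(1.3, thr$ratio_cutoff, Inf)),
    III = list(cd4 = c(950, thr$cd4_high, Inf), ratio = c(0.8, 0, thr$ratio_cutoff)),
    IVa = list(cd4 = c(640, b[1], thr$cd4_high), ratio = c(0.75, 0, thr$ratio_cutoff)),
    IVb = list(cd4 = c(340, b[2], b[1]), ratio = c(0.7, 0, thr$ratio_cutoff)),
    IVc = list(cd4 = c(120, 0, b[2]), ratio = c(0.6, 0, thr$ratio_cutoff)))
  if (any(vapply(props, function(p) p$cd4[1], 0) <= 0))
    stop("count locations must be positive", call. = FALSE)
  rtrunc_ln <- function(m, location, lo, hi, sdlog) {
    out <- numeric(m)
    todo <- seq_len(m)
    while (length(todo)) {
      x <- stats::rlnorm(length(todo), log(location), sdlog)
      ok <- x >= lo & x < hi
      out[todo[ok]] <- x[ok]
      todo <- todo[!ok]
    }
    out
  }
  n <- config$n_subjects
  with_seed(substream_seed(config$seed, "counts"), {
    grade <- sample(names(config$grade_prevalences), n, replace = TRUE,
                    prob = config$grade_prevalences)
    cd4 <- cd8 <- numeric(n)
    for (g in unique(grade)) {
      ix <- which(grade == g); pr <- props[[g]]
      cd4[ix] <- rtrunc_ln(length(ix), pr$cd4[1], pr$cd4[2], pr$cd4[3], 0.25)
      ratio <- rtrunc_ln(length(ix), pr$ratio[1], pr$ratio[2], pr$ratio[3], 0.3)
      cd8[ix] <- cd4[ix] / ratio
    }
    structure(data.frame(cd4 = cd4, cd8 = cd8),
              truth = data.frame(subject = sprintf("S%05d", seq_len(n)),
                                 grade = factor(grade, levels = ihg_levels())))
  })
}

#' Generate a protein-abundance table with planted score associations
#'
#' The first `n_true_sas` proteins are linear in the SAS-1 score, the next
#' `n_true_mas` in the MAS-1 score, the next `n_shared` in both; the
#' remainder is pure noise. Effect size and noise sd come from
#' `config$proteomic_spec`.
#'
#' @param config a [sim_config()].
#' @param sas_scores,mas_scores per-sample signature scores (z-units).
#' @return samples x proteins matrix with attribute `truth` (data.frame
#'   `protein`, `assoc` in `{SAS, MAS, both, none}`).
#' @export
gen_proteomics <- function(config, sas_scores, mas_scores) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(sas_scores)
  if (length(mas_scores) != n)
    stop("score vectors differ in length", call. = FALSE)
  ps <- config$proteomic_spec
  assoc <- rep(c("SAS", "MAS", "both", "none"),
               c(ps$n_true_sas, ps$n_true_mas, ps$n_shared,
                 ps$n_proteins - ps$n_true_sas - ps$n_true_mas - ps$n_shared))
  ids <- sprintf("P%04d", seq_len(ps$n_proteins))
  with_seed(substream_seed(config$seed, "proteomics"), {
    mat <- matrix(stats::rnorm(n * ps$n_proteins, sd = ps$noise_sd),
                  nrow = n, dimnames = list(names(sas_scores), ids))
    s_load <- ps$effect * (assoc %in% c("SAS", "both"))
    m_load <- ps$effect * (assoc %in% c("MAS", "both"))
    mat <- mat + outer(as.numeric(sas_scores), s_load) +
      outer(as.numeric(mas_scores), m_load)
    structure(mat, truth = data.frame(protein = ids, assoc = assoc))
  })
}

#' Simulate a full cohort
#'
#' Runs all generators under one seed: phenotype base, expression with
#' planted signatures, measured SAS-1/MAS-1 scores and IR profiles (via the
#' pipeline's own scorer on the generated matrix), T-cell counts, survival
#' times keyed to the measured profile, and a protein table keyed to the
#' measured scores.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort`: `expression`, `phenotypes`
#'   (subject, age, sex, cd4, cd8, time, event), `scores`, `profile`,
#'   `signatures`, `truth`, `proteomics`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  base <- gen_phenotype_base(config)
  expr <- gen_expression(config, ages = base$age, sex = base$sex)
  sigs <- attr(expr, "signatures")
  truth_expr <- attr(expr, "truth")
  z <- suppressWarnings(zscore_genes(expr))
  sas <- score_signature(z, sigs[["SAS-1"]])
  mas <- score_signature(z, sigs[["MAS-1"]])
  profile <- make_profile(stratify(sas), stratify(mas))
  counts <- gen_counts(config)
  surv <- gen_survival(config, ages = base$age, groups = as.character(profile))
  prot <- gen_proteomics(config, sas, mas)
  phenotypes <- data.frame(base, cd4 = counts$cd4, cd8 = counts$cd8,
                           time = surv$time, event = surv$event)
  truth <- merge(truth_expr, attr(counts, "truth"), by = "subject")
  truth$baseline_rate <- attr(surv, "baseline_rate")
  structure(list(expression = expr, phenotypes = phenotypes,
                 scores = list(`SAS-1` = sas, `MAS-1` = mas),
                 profile = profile, signatures = sigs, truth = truth,
                 proteomics = prot, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d genes, %d proteins\n",
              nrow(x$phenotypes), nrow(x$expression), ncol(x$proteomics)))
  print(table(profile = x$profile))
  invisible(x)
}
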
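# End-to-end pipeline: score -> stratify -> profile -> triad ->
# (ihg, trajectory) -> survival -> screen, with a JSON run summary.

#' Pipeline configuration
#'
#' @param expression path to the expression matrix (TSV) or an in-memory
#'   matrix.
#' @param gene_sets path to a GMT file or an in-memory list of
#'   [gene_signature()]s; must contain `sas` and `mas` and, for the triad
#'   stage, the six readout signatures.
#' @param phenotypes path to a CSV (columns `subject`, and as available
#'   `age`, `sex`, `cd4`, `cd8`, `time`, `event`, `timepoint`) or a
#'   data.frame.
#' @param sas,mas names of the SAS-1/MAS-1 signatures in `gene_sets`.
#' @param min_coverage scorer coverage threshold.
#' @param aggregator scorer aggregator (`"mean"`, `"median"`, `"ranksum"`).
#' @param ihg [ihg_thresholds()].
#' @param ref_age reference age for the equivalence-age statistic.
#' @param fdr screen FDR level in (0, 1).
#' @param seed integer seed recorded with every output.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, gene_sets, phenotypes,
                            sas = "SAS-1", mas = "MAS-1",
                            min_coverage = 0.8, aggregator = "mean",
                            ihg = ihg_thresholds(), ref_age = 40,
                            fdr = 0.05, seed = 1L) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0,1)", call. = FALSE)
  for (p in list(expression, gene_sets, phenotypes))
    if (is.character(p) && length(p) == 1L && !file.exists(p))
      stop("path does not exist: ", p, call. = FALSE)
  structure(list(expression = expression, gene_sets = gene_sets,
                 phenotypes = phenotypes, sas = sas, mas = mas,
                 min_coverage = min_coverage, aggregator = aggregator,
                 ihg = ihg, ref_age = ref_age, fdr = fdr,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full IR pipeline
#'
#' Executes every stage the inputs support and writes per-stage TSVs plus a
#' JSON summary (carrying the config hash and seed) to `out_dir` when given.
#' Stages needing absent phenotype columns (e.g. `cd4`/`cd8` for IHG,
#' `time`/`event` for survival) are skipped and logged.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with per-stage results (`scores`, `strata`, `profile`,
#'   `burden`, `ihg`, `trajectories`, `survival`, `summary`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  expr <- if (is.character(config$expression))
    read_expression(config$expression) else
      as_expression_matrix(config$expression)
  sigs <- if (is.character(config$gene_sets))
    read_gmt(config$gene_sets) else config$gene_sets
  pheno <- if (is.character(config$phenotypes))
    utils::read.csv(config$phenotypes, stringsAsFactors = FALSE) else
      as.data.frame(config$phenotypes)
  if (!"subject" %in% names(pheno))
    stop("phenotype table lacks required column: subject", call. = FALSE)
  for (nm in c(config$sas, config$mas))
    if (!nm %in% names(sigs))
      stop("gene sets lack required signature: ", nm, call. = FALSE)

  z <- zscore_genes(expr)
  scores <- lapply(sigs, function(s)
    score_signature(z, s, min_coverage = config$min_coverage,
                    aggregator = config$aggregator))
  sas <- scores[[config$sas]]; mas <- scores[[config$mas]]
  strata <- list(sas = stratify(sas), mas = stratify(mas))
  profile <- make_profile(strata$sas, strata$mas)

  roles <- vapply(sigs, `[[`, "", "role")
  burden <- NULL
  if (sum(roles == "pos-salutogenesis") >= 1 &&
      sum(roles == "neg-salutogenesis") >= 1) {
    panel <- readout_panel(pos = scores[roles == "pos-salutogenesis"],
                           neg = scores[roles == "neg-salutogenesis"])
    burden <- triad_burden(panel)
  }

  ord <- match(colnames(expr), pheno$subject)
  pheno_m <- pheno[ord, , drop = FALSE]
  ihg_res <- NULL
  if (all(c("cd4", "cd8") %in% names(pheno)) &&
      !anyNA(pheno_m$cd4) && !anyNA(pheno_m$cd8)) {
    g <- assign_ihg(pheno_m$cd4, pheno_m$cd8, config$ihg)
    ihg_res <- data.frame(subject = pheno_m$subject, grade = g,
                          extreme_degrader = is_extreme_degrader(g))
  } else ir_log("IHG stage skipped (cd4/cd8 unavailable)")

  traj <- NULL
  if ("timepoint" %in% names(pheno)) {
    long <- data.frame(subject = pheno_m$subject,
                       timepoint = pheno_m$timepoint,
                       profile = profile)
    traj <- classify_trajectories(long)
  }

  surv_res <- NULL
  if (all(c("time", "event", "age") %in% names(pheno)) &&
      !anyNA(pheno_m$time)) {
    sdat <- data.frame(time = pheno_m$time, event = pheno_m$event,
                       age = pheno_m$age,
                       degraded = as.integer(profile == "L-H"))
    if ("sex" %in% names(pheno_m)) sdat$sex <- pheno_m$sex
    keep <- profile %in% c("H-L", "L-H")
    fit <- tryCatch(
      fit_ph(sdat[keep, ], covariates = c("age", "degraded",
                                          intersect("sex", names(sdat)))),
      error = function(e) { ir_log("survival stage failed: %s",
                                   conditionMessage(e)); NULL })
    if (!is.null(fit)) {
      eq <- tryCatch(equivalence_age(fit, "degraded", "age",
                                     ref_age = config$ref_age),
                     error = function(e) NULL)
      surv_res <- list(fit = fit,
                       hr = hazard_ratio(fit, "degraded"),
                       equivalence = eq)
    }
  } else ir_log("survival stage skipped (time/event/age unavailable)")

  summary <- list(
    config_hash = config_hash(config[setdiff(names(config),
                                             c("expression", "gene_sets",
                                               "phenotypes"))]),
    seed = config$seed,
    n_samples = ncol(expr), n_genes = nrow(expr),
    n_signatures = length(sigs),
    profile_counts = as.list(table(profile)),
    stages_run = c("score", "stratify", "profile",
                   if (!is.null(burden)) "triad",
                   if (!is.null(ihg_res)) "ihg",
                   if (!is.null(traj)) "trajectory",
                   if (!is.null(surv_res)) "survive"))
  res <- list(scores = scores, strata = strata, profile = profile,
              burden = burden, ihg = ihg_res, trajectories = traj,
              survival = surv_res, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    per_sample <- data.frame(sample = names(sas),
                             sas_score = sas, mas_score = mas,
                             sas_stratum = strata$sas,
                             mas_stratum = strata$mas, profile = profile)
    if (!is.null(burden)) per_sample$triad_burden <- burden
    write_tsv(format(per_sample, digits = 15, trim = TRUE),
              file.path(out_dir, "per_sample.tsv"))
    if (!is.null(ihg_res)) write_tsv(ihg_res, file.path(out_dir, "ihg.tsv"))
    if (!is.null(traj)) write_tsv(traj, file.path(out_dir, "trajectories.tsv"))
    report <- summary
    if (!is.null(surv_res)) {
      report$survival <- list(
        coefficients = as.list(surv_res$fit$coefficients),
        hr_degraded = surv_res$hr$hr,
        equivalence_age = surv_res$equivalence$equivalence_age,
        survival_gap = surv_res$equivalence$gap)
    }
    jsonlite::write_json(report, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
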
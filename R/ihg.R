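# Immune health grades (IHG) from absolute CD4+/CD8+ T-cell counts.

#' IHG threshold set
#'
#' The grading logic crosses the CD4:CD8 ratio against the absolute CD4
#' count: grade I/II when the ratio is at or above `ratio_cutoff`, III/IV
#' below it; the `I` vs `II` (and `III` vs `IV`) split is `cd4_high`.
#' Grades II and IV are subgraded a/b/c by descending CD4 bands
#' (`a >= bands[1]`, `b` in `[bands[2], bands[1])`, `c < bands[2]`).
#' Defaults reconstruct the published qualitative description and are fully
#' configurable; every result records the thresholds used.
#'
#' @param ratio_cutoff CD4:CD8 ratio cutoff (default 1.0).
#' @param cd4_high CD4 cells/uL separating I/III from II/IV (default 800).
#' @param subgrade_bands two descending CD4 edges for a/b/c (default 500, 200).
#' @return object of class `ihg_thresholds`.
#' @export
ihg_thresholds <- function(ratio_cutoff = 1.0, cd4_high = 800,
                           subgrade_bands = c(500, 200)) {
  stopifnot(length(subgrade_bands) == 2L)
  if (!(ratio_cutoff > 0 && cd4_high > 0 && all(subgrade_bands > 0)))
    stop("IHG thresholds must be positive", call. = FALSE)
  if (diff(subgrade_bands) >= 0)
    stop("subgrade_bands must be strictly decreasing", call. = FALSE)
  if (subgrade_bands[1] >= cd4_high)
    stop("subgrade bands must lie below cd4_high", call. = FALSE)
  structure(list(ratio_cutoff = ratio_cutoff, cd4_high = cd4_high,
                 subgrade_bands = as.numeric(subgrade_bands)),
            class = "ihg_thresholds")
}

#' Assign immune health grades from CD4/CD8 counts
#'
#' Total over positive counts: every (cd4, cd8) pair maps to exactly one of
#' the eight grades. IHG-I captures high CD4 with restrained CD8 expansion
#' (ratio >= cutoff, CD4 >= `cd4_high`); IHG-III the same CD4 preservation
#' with CD8 expansion; II and IV their CD4-depleted counterparts, subgraded
#' a/b/c by CD4 bands. Boundary convention: `>=` on the high side of every
#' cutoff.
#'
#' @param cd4,cd8 absolute counts in cells/uL (vectors, recycled pairwise).
#' @param thr an [ihg_thresholds()] object.
#' @return factor of grades with levels [ihg_levels()]; attribute
#'   `thresholds` records `thr`.
#' @export
assign_ihg <- function(cd4, cd8, thr = ihg_thresholds()) {
  stopifnot(inherits(thr, "ihg_thresholds"))
  n <- max(length(cd4), length(cd8))
  cd4 <- rep_len(as.numeric(cd4), n); cd8 <- rep_len(as.numeric(cd8), n)
  if (any(!is.finite(cd4)) || any(!is.finite(cd8)) ||
      any(cd4 <= 0) || any(cd8 <= 0))
    stop("CD4/CD8 counts must be positive and finite", call. = FALSE)
  ratio <- cd4 / cd8
  hi_ratio <- ratio >= thr$ratio_cutoff
  hi_cd4 <- cd4 >= thr$cd4_high
  sub <- ifelse(cd4 >= thr$subgrade_bands[1], "a",
                ifelse(cd4 >= thr$subgrade_bands[2], "b", "c"))
  lab <- ifelse(hi_ratio,
                ifelse(hi_cd4, "I", paste0("II", sub)),
                ifelse(hi_cd4, "III", paste0("IV", sub)))
  structure(factor(lab, levels = ihg_levels()), thresholds = thr)
}

#' Extreme IR-degrader flag
#'
#' Patients presenting with IHG-IIc or IHG-IVc — profound CD4 depletion on
#' either side of the ratio cutoff — are classified as extreme IR-degraders.
#'
#' @param grade factor/character of IHG grades.
#' @return logical vector.
#' @export
is_extreme_degrader <- function(grade) {
  as.character(grade) %in% c("IIc", "IVc")
}

#' Grade prevalence table
#'
#' @param grades factor of IHG grades (or any categorical label).
#' @param strata optional grouping factor; prevalences are per group.
#' @return data.frame with columns `group` (if stratified), `grade`, `n`,
#'   `prevalence`; per-group prevalences sum to 1.
#' @export
grade_prevalence <- function(grades, strata = NULL) {
  grades <- as.factor(grades)
  if (is.null(strata)) strata <- factor(rep("all", length(grades)))
  strata <- as.factor(strata)
  if (length(strata) != length(grades))
    stop("strata and grades differ in length", call. = FALSE)
  if (any(table(strata) == 0L))
    stop("empty group in strata: ",
         paste(levels(strata)[table(strata) == 0L], collapse = ", "),
         call. = FALSE)
  tab <- table(group = strata, grade = grades)
  prev <- prop.table(tab, margin = 1L)
  out <- as.data.frame(tab, responseName = "n")
  out$prevalence <- as.data.frame(prev)$Freq
  out
}

#' Logistic model of non-optimal grade prevalence on age
#'
#' Fits `P(grade != reference_grade) ~ age` by logistic regression and
#' returns the per-year log-odds slope with Wald confidence limits plus a
#' band function for plotting fitted prevalence against age.
#'
#' @param grades factor of grades.
#' @param ages numeric ages (years).
#' @param reference_grade the optimal grade (default `"I"`).
#' @param level confidence level (default 0.95).
#' @return list with `intercept`, `slope`, `slope_ci`, `fit` (the glm), and
#'   `band(age)` returning fitted prevalence with lower/upper limits.
#' @export
prevalence_vs_age <- function(grades, ages, reference_grade = "I",
                              level = 0.95) {
  y <- as.integer(as.character(grades) != reference_grade)
  if (length(y) != length(ages))
    stop("grades and ages differ in length", call. = FALSE)
  if (all(y == 0L) || all(y == 1L))
    stop("all subjects on one side of reference grade; logistic fit is ",
         "separated", call. = FALSE)
  df <- data.frame(y = y, age = as.numeric(ages))
  fit <- stats::glm(y ~ age, family = stats::binomial(), data = df)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  band <- function(age) {
    p <- stats::predict(fit, newdata = data.frame(age = age), se.fit = TRUE)
    data.frame(age = age,
               prevalence = stats::plogis(p$fit),
               lower = stats::plogis(p$fit - zq * p$se.fit),
               upper = stats::plogis(p$fit + zq * p$se.fit))
  }
  list(intercept = unname(co[1]), slope = unname(co[2]),
       slope_ci = unname(co[2] + c(-1, 1) * zq * se[2]),
       fit = fit, band = band)
}
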
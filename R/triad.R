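# Pathogenic-triad burden: composite of the six salutogenesis readouts.

#' Bundle the six salutogenesis readouts into a panel
#'
#' `pos` holds the positive-salutogenesis readouts (higher = less immune
#' aging; e.g. IMM-AGE, EL-down, t-TCH-high roles) and `neg` the negative
#' ones (higher = more inflammaging / senescent-cell burden; e.g. Age_IL6-up,
#' InflammAge-up, SenMayo roles). Scores must be aligned on identical sample
#' names. Weights default to 1 per readout.
#'
#' @param pos,neg named lists of per-sample score vectors (z-units).
#' @param weights_pos,weights_neg nonnegative weights, one per readout.
#' @return object of class `readout_panel`.
#' @export
readout_panel <- function(pos, neg,
                          weights_pos = rep(1, length(pos)),
                          weights_neg = rep(1, length(neg))) {
  if (length(pos) < 1L || length(neg) < 1L)
    stop("both panel sides must be nonempty", call. = FALSE)
  w <- c(weights_pos, weights_neg)
  if (any(!is.finite(w)) || any(w < 0) || all(w == 0))
    stop("weights must be finite, nonnegative and not all zero", call. = FALSE)
  all_scores <- c(pos, neg)
  ids <- names(all_scores[[1]])
  for (s in all_scores) {
    if (is.null(names(s)) || length(s) != length(ids) ||
        !identical(names(s), ids))
      stop("readouts are not aligned on the same samples", call. = FALSE)
    assert_finite(s, "readout score")
  }
  structure(list(pos = pos, neg = neg,
                 weights_pos = as.numeric(weights_pos),
                 weights_neg = as.numeric(weights_neg),
                 sample_ids = ids),
            class = "readout_panel")
}

#' Pathogenic-triad burden score
#'
#' Continuous mode (default): weighted mean of the negative readouts minus
#' the weighted mean of the positive readouts, per sample — higher burden
#' means more inflammaging/senescence and less immunocompetence. Count mode:
#' the number of readouts (0-6 under the default panel) falling in their
#' unfavourable median half (neg above its median, pos at or below its
#' median), stratified against `reference` cohort medians when supplied.
#'
#' @param panel a [readout_panel()].
#' @param mode `"continuous"` or `"count"`.
#' @param reference optional `readout_panel` supplying the medians for count
#'   mode (defaults to `panel` itself).
#' @return named numeric vector of burdens, one per sample.
#' @export
triad_burden <- function(panel, mode = c("continuous", "count"),
                         reference = NULL) {
  stopifnot(inherits(panel, "readout_panel"))
  mode <- match.arg(mode)
  pos_mat <- do.call(rbind, panel$pos)
  neg_mat <- do.call(rbind, panel$neg)
  if (mode == "continuous") {
    wp <- panel$weights_pos / sum(panel$weights_pos)
    wn <- panel$weights_neg / sum(panel$weights_neg)
    burden <- as.numeric(crossprod(neg_mat, wn) - crossprod(pos_mat, wp))
  } else {
    if (is.null(reference)) reference <- panel
    adverse <- function(scores, ref_scores, unfavourable_high) {
      m <- stats::median(ref_scores)
      if (unfavourable_high) scores > m else scores <= m
    }
    bad <- mapply(adverse, panel$neg, reference$neg,
                  MoreArgs = list(unfavourable_high = TRUE))
    bad_pos <- mapply(adverse, panel$pos, reference$pos,
                      MoreArgs = list(unfavourable_high = FALSE))
    burden <- as.numeric(rowSums(cbind(bad, bad_pos)))
  }
  stats::setNames(burden, panel$sample_ids)
}

#' Group contrasts of triad burden (or any readout)
#'
#' Ordinary linear model of `burden ~ grouping + covariates`; returns the
#' mean-difference estimate (beta) per non-reference group level with Wald
#' confidence limits and a likelihood-ratio p-value against the
#' grouping-free null. Covers the older-vs-younger and
#' degraded-vs-optimal-profile contrasts in one call.
#'
#' @param burden numeric response per sample.
#' @param grouping factor (first level is the reference).
#' @param covariates optional data.frame of adjustment covariates.
#' @param level confidence level.
#' @return data.frame with columns `contrast`, `beta`, `lower`, `upper`,
#'   `p_lrt`.
#' @export
burden_contrast <- function(burden, grouping, covariates = NULL,
                            level = 0.95) {
  grouping <- droplevels(as.factor(grouping))
  if (nlevels(grouping) < 2L)
    stop("grouping has a single level; no contrast to estimate", call. = FALSE)
  df <- data.frame(burden = as.numeric(burden), grouping = grouping)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  rhs_cov <- if (is.null(covariates)) "1" else
    paste(colnames(covariates), collapse = " + ")
  full <- stats::lm(stats::reformulate(c("grouping", rhs_cov), "burden"), df)
  null <- stats::lm(stats::reformulate(rhs_cov, "burden"), df)
  lrt <- stats::anova(null, full)
  p_lrt <- lrt$`Pr(>F)`[2]
  co <- summary(full)$coefficients
  idx <- grep("^grouping", rownames(co))
  zq <- stats::qt(1 - (1 - level) / 2, df = full$df.residual)
  data.frame(contrast = paste0(sub("^grouping", "", rownames(co)[idx]),
                               " vs ", levels(grouping)[1]),
             beta = co[idx, 1], lower = co[idx, 1] - zq * co[idx, 2],
             upper = co[idx, 1] + zq * co[idx, 2],
             p_lrt = p_lrt, row.names = NULL)
}
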
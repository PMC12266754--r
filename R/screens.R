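# FDR-controlled association screens and small contingency utilities.

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment: `q_i = min_{j: p_(j) >= p_(i)} p_(j) * m / rank(j)`,
#' clipped at 1 and mapped back to input order. Implemented directly (not
#' via [stats::p.adjust()]) so the test suite can cross-check the two.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  p <- as.numeric(pvals)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- cummin(rev(p[o] * m / seq_len(m)))  # from largest p downwards
  q <- numeric(m)
  q[o] <- pmin(rev(q_sorted), 1)
  q
}

#' Mass-univariate association screen with BH correction
#'
#' One regression per feature. Linear family (the transcription-factor and
#' proteomic screens): the feature is the outcome,
#' `feature ~ response + covariates`, fitted for all features at once from a
#' single QR decomposition of the shared design. Logistic family: the
#' (binary) response is the outcome, `response ~ feature + covariates`,
#' fitted per feature. Either way the reported effect is the
#' response/feature coefficient with its Wald p, and `q` is [bh_fdr()] over
#' all features.
#'
#' @param features numeric matrix, samples x features (column names are
#'   feature ids).
#' @param response numeric (linear) or 0/1 (logistic) vector per sample.
#' @param covariates optional data.frame/matrix of adjustment covariates
#'   (e.g. age, sex).
#' @param family `"linear"` or `"logistic"`.
#' @return data.frame (`screen_rows`): `feature`, `beta`, `se`, `p`, `q`,
#'   in input column order.
#' @export
screen_features <- function(features, response, covariates = NULL,
                            family = c("linear", "logistic")) {
  family <- match.arg(family)
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("F", seq_len(ncol(features)))
  n <- nrow(features)
  if (length(response) != n)
    stop("response and features are not aligned on samples", call. = FALSE)
  cov_mat <- NULL
  if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)
    cov_mat <- stats::model.matrix(~ ., data = cov_df)[, -1, drop = FALSE]
  }
  if (family == "linear") {
    X <- cbind(`(Intercept)` = 1, response = as.numeric(response), cov_mat)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("rank-deficient design; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    coefs <- qr.coef(qrX, features)          # p x m
    resid <- qr.resid(qrX, features)
    dfres <- n - ncol(X)
    if (dfres < 1L) stop("no residual degrees of freedom", call. = FALSE)
    sigma2 <- colSums(resid^2) / dfres
    xtx_inv <- chol2inv(qr.R(qrX))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    beta <- coefs["response", ]
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df = dfres)
  } else {
    if (!all(response %in% c(0, 1)))
      stop("logistic family needs a 0/1 response", call. = FALSE)
    beta <- se <- p <- numeric(ncol(features))
    for (j in seq_len(ncol(features))) {
      df <- data.frame(y = response, x = features[, j])
      if (!is.null(cov_mat)) df <- cbind(df, cov_mat)
      fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
      s <- summary(fit)$coefficients
      beta[j] <- s["x", 1]; se[j] <- s["x", 2]; p[j] <- s["x", 4]
    }
  }
  out <- data.frame(feature = colnames(features), beta = unname(beta),
                    se = unname(se), p = unname(p))
  out$q <- bh_fdr(out$p)
  class(out) <- c("screen_rows", "data.frame")
  out
}

#' Set overlap with counts
#'
#' Exact set algebra for comparing two discovery lists (e.g. SAS-1- vs
#' MAS-1-associated proteins).
#'
#' @param setA,setB character vectors (duplicates removed).
#' @return list: `shared`, `onlyA`, `onlyB` plus `n_shared`, `n_onlyA`,
#'   `n_onlyB`.
#' @export
overlap_sets <- function(setA, setB) {
  a <- unique(as.character(setA)); b <- unique(as.character(setB))
  shared <- intersect(a, b)
  list(shared = shared, onlyA = setdiff(a, b), onlyB = setdiff(b, a),
       n_shared = length(shared), n_onlyA = length(setdiff(a, b)),
       n_onlyB = length(setdiff(b, a)))
}

#' Quantile-bin dose-response of a label on a score
#'
#' Bins the score into `n_bins` equal-count quantile bins (octiles by
#' default; ties fall in the lower bin) and reports per-bin profile
#' fractions, plus a logistic regression of `P(label == target)` on the raw
#' score (log-odds per score unit).
#'
#' @param score numeric per-sample score (e.g. TCF7 normalized expression).
#' @param labels factor of IR profiles (or any categorical label).
#' @param n_bins number of quantile bins (default 8).
#' @param target label whose odds are modelled (default `"H-L"`).
#' @param level confidence level.
#' @return list: `prevalence` (data.frame bin x label fractions summing to 1
#'   per bin), `slope`, `slope_ci`, `p`, `fit`.
#' @export
dose_response <- function(score, labels, n_bins = 8, target = "H-L",
                          level = 0.95) {
  n <- length(score)
  if (length(labels) != n)
    stop("score and labels differ in length", call. = FALSE)
  if (n < n_bins)
    stop("need at least n_bins samples (", n_bins, "), got ", n,
         call. = FALSE)
  # equal-count bins; ties share the rank minimum hence the lower bin
  r <- rank(score, ties.method = "min")
  bin <- floor((r - 1) * n_bins / n) + 1L
  bin <- pmin(bin, n_bins)
  tab <- prop.table(table(bin = bin, label = labels), margin = 1L)
  prevalence <- as.data.frame(tab, responseName = "fraction")
  y <- as.integer(as.character(labels) == target)
  fit <- stats::glm(y ~ score, family = stats::binomial())
  s <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(prevalence = prevalence,
       slope = s["score", 1],
       slope_ci = s["score", 1] + c(-1, 1) * zq * s["score", 2],
       p = s["score", 4], fit = fit)
}

#' Summaries of a 2x2 contingency table
#'
#' Row-wise outcome proportions (first column over row total), odds ratio
#' `(a*d)/(b*c)` with the Haldane-Anscombe 0.5 correction applied only when
#' a zero cell is present, two-sided Fisher exact p (summing tables with
#' probability at most that observed) and the chi-square p (without
#' continuity correction).
#'
#' @param tab 2x2 matrix of nonnegative integer counts (rows = groups,
#'   columns = outcome yes/no).
#' @return list: `proportions`, `odds_ratio`, `fisher_p`, `chisq_p`, `table`.
#' @export
summarize_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("table must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)) || sum(tab) == 0)
    stop("cells must be nonnegative integers with a positive total",
         call. = FALSE)
  props <- tab[, 1] / rowSums(tab)
  work <- tab
  if (any(tab == 0)) work <- tab + 0.5
  or <- (work[1, 1] * work[2, 2]) / (work[1, 2] * work[2, 1])
  fisher_p <- stats::fisher.test(tab)$p.value
  chisq_p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  list(proportions = unname(props), odds_ratio = unname(or),
       fisher_p = fisher_p, chisq_p = chisq_p, table = tab)
}
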
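# Signature scoring, median-split strata, IR profiles, TCF7 status.

#' Construct an oriented gene signature
#'
#' A signature is a named set of genes, each carrying an orientation: `+1`
#' members contribute positively to the composite score, `-1` members
#' negatively (e.g. genes whose *lower* expression marks the favourable
#' state). Roles tag how a signature is used downstream: the two IR metrics
#' (SAS-1, MAS-1), the three positive-salutogenesis readouts (higher = less
#' immune aging), the three negative-salutogenesis readouts (higher = more
#' inflammaging/senescent burden), or a single-gene marker such as TCF7.
#'
#' @param name signature name (nonempty).
#' @param genes character vector of gene identifiers (no duplicates).
#' @param orientation `+1`/`-1` per gene; scalar recycled.
#' @param role one of `"IR-metric"`, `"pos-salutogenesis"`,
#'   `"neg-salutogenesis"`, `"single-gene"`.
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, orientation = 1L,
                           role = c("IR-metric", "pos-salutogenesis",
                                    "neg-salutogenesis", "single-gene")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("signature name must be a nonempty string", call. = FALSE)
  if (length(genes) < 1L)
    stop("signature '", name, "' must have at least one member", call. = FALSE)
  if (anyDuplicated(genes))
    stop("signature '", name, "' lists duplicated genes: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  orientation <- as.integer(rep_len(orientation, length(genes)))
  if (!all(orientation %in% c(-1L, 1L)))
    stop("orientations must be +1 or -1", call. = FALSE)
  structure(list(name = name, genes = as.character(genes),
                 orientation = orientation, role = role),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s [%s]: %d genes (%d oriented -1)\n",
              x$name, x$role, length(x$genes), sum(x$orientation == -1L)))
  invisible(x)
}

#' Gene-wise z-scoring of an expression matrix
#'
#' Standardises every gene (row) to mean 0, sd 1 across samples, using the
#' sample standard deviation (denominator n-1). Zero-variance genes cannot be
#' standardised; they are dropped with a warning.
#'
#' @param expr numeric matrix, genes x samples, with unique dimnames.
#' @return z-scored matrix (possibly fewer rows).
#' @export
zscore_genes <- function(expr) {
  expr <- as_expression_matrix(expr)
  if (ncol(expr) < 2L)
    stop("z-scoring needs at least 2 samples (sd undefined)", call. = FALSE)
  mu <- rowMeans(expr)
  centred <- expr - mu
  sdv <- sqrt(rowSums(centred^2) / (ncol(expr) - 1L))
  keep <- sdv > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance gene(s) dropped: ",
            paste(utils::head(rownames(expr)[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "", call. = FALSE)
  }
  centred[keep, , drop = FALSE] / sdv[keep]
}

# Validate the genes x samples contract shared by all consumers.
as_expression_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) stop("expression must be numeric", call. = FALSE)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  assert_finite(expr, "expression matrix")
  expr
}

#' Composite signature score per sample
#'
#' The default composite is the unweighted mean over present members of
#' `orientation * z(gene, sample)`; `aggregator` swaps in a median or
#' rank-sum variant. Coverage below `min_coverage` (fraction of members found
#' among the matrix rows) is an error that names the missing genes.
#'
#' @param z_expr z-scored expression matrix (see [zscore_genes()]).
#' @param sig [gene_signature()].
#' @param min_coverage minimum fraction of members that must be present.
#' @param aggregator `"mean"` (default), `"median"` or `"ranksum"`.
#' @return named numeric vector, one score per sample (z-units).
#' @export
score_signature <- function(z_expr, sig, min_coverage = 0.8,
                            aggregator = c("mean", "median", "ranksum")) {
  aggregator <- match.arg(aggregator)
  z_expr <- as_expression_matrix(z_expr)
  stopifnot(inherits(sig, "gene_signature"))
  present <- sig$genes %in% rownames(z_expr)
  coverage <- mean(present)
  if (coverage < min_coverage)
    stop(sprintf(
      "signature '%s': coverage %.2f below %.2f; missing: %s",
      sig$name, coverage, min_coverage,
      paste(utils::head(sig$genes[!present], 10L), collapse = ", ")),
      call. = FALSE)
  sub <- z_expr[sig$genes[present], , drop = FALSE]
  oriented <- sub * sig$orientation[present]
  scores <- switch(aggregator,
    mean    = colMeans(oriented),
    median  = apply(oriented, 2L, stats::median),
    # rank-sum: per-gene cross-sample ranks, averaged; centred to z-like scale
    ranksum = {
      r <- t(apply(oriented, 1L, rank, ties.method = "average"))
      colMeans((r - (ncol(oriented) + 1) / 2) / stats::sd(seq_len(ncol(oriented))))
    })
  stats::setNames(as.numeric(scores), colnames(z_expr))
}

#' Median-split stratification
#'
#' Labels each score `H` iff it exceeds the reference median and `L`
#' otherwise; a score exactly at the median is `L`. The reference defaults to
#' the scored cohort itself; pass e.g. the baseline-timepoint scores to judge
#' follow-up samples against baseline.
#'
#' @param score numeric scores.
#' @param reference optional numeric reference scores for the median.
#' @return factor with levels `H`, `L`, named like `score`.
#' @export
stratify <- function(score, reference = NULL) {
  if (is.null(reference)) reference <- score
  if (length(reference) < 2L)
    stop("stratify needs at least 2 reference values", call. = FALSE)
  assert_finite(score, "scores"); assert_finite(reference, "reference scores")
  m <- stats::median(reference)
  f <- factor(ifelse(score > m, "H", "L"), levels = c("H", "L"))
  names(f) <- names(score)
  f
}

#' Combine SAS-1 and MAS-1 strata into IR profiles
#'
#' Labels are `SAS-1 stratum`-`MAS-1 stratum`: `H-L` marks optimal IR,
#' `L-H` extreme IR degradation.
#'
#' @param sas_stratum,mas_stratum factors from [stratify()], same length.
#' @return factor with levels from [ir_profile_levels()].
#' @export
make_profile <- function(sas_stratum, mas_stratum) {
  if (length(sas_stratum) != length(mas_stratum))
    stop("SAS and MAS strata differ in length", call. = FALSE)
  lab <- paste0(as.character(sas_stratum), "-", as.character(mas_stratum))
  lab[is.na(sas_stratum) | is.na(mas_stratum)] <- NA
  f <- factor(lab, levels = ir_profile_levels())
  names(f) <- names(sas_stratum)
  f
}

#' TCF7 level and stratum
#'
#' Returns the raw normalized expression of a single gene (TCF7 by default)
#' together with its median-split H/L call across the cohort.
#'
#' @param expr expression matrix on the normalized (not z-scored) scale.
#' @param gene_id gene row to use.
#' @return list with `level` (numeric per sample) and `stratum` (H/L factor).
#' @export
tcf7_status <- function(expr, gene_id = "TCF7") {
  expr <- as_expression_matrix(expr)
  if (!gene_id %in% rownames(expr))
    stop("gene '", gene_id, "' absent from expression matrix", call. = FALSE)
  lev <- expr[gene_id, ]
  list(level = lev, stratum = stratify(lev))
}

#' Pearson correlation matrix of signature scores with clustering order
#'
#' Correlates all supplied score vectors (plus an optional age vector) and
#' orders them by average-linkage hierarchical clustering on distance `1 - r`.
#'
#' @param scores named list of equal-length score vectors.
#' @param extra optional named numeric vector (e.g. age) appended as a row.
#' @return list with `r` (symmetric correlation matrix), `order` (integer
#'   clustering order) and `hclust` (the tree).
#' @export
signature_correlation_matrix <- function(scores, extra = NULL) {
  stopifnot(is.list(scores), length(scores) >= 2L)
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be a named list", call. = FALSE)
  mat <- do.call(cbind, scores)
  if (!is.null(extra)) mat <- cbind(mat, age = extra)
  r <- stats::cor(mat)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(r = r, order = hc$order, hclust = hc)
}
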
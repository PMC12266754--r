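# Readers/writers for expression matrices (TSV, MTX triplet) and GMT
# gene sets with the paired NAME_UP / NAME_DN orientation dialect.

#' Read an expression matrix
#'
#' TSV layout: header row of sample ids, first column gene ids. MTX layout:
#' a Matrix-Market triplet file plus sibling annotation files holding the
#' row (gene) and column (sample) ids, one per line (defaults
#' `<path>.rows` / `<path>.cols`).
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @param rows,cols annotation paths for the mtx format.
#' @return numeric genes x samples matrix.
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            rows = paste0(path, ".rows"),
                            cols = paste0(path, ".cols")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop("duplicate gene ids in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    storage.mode(m) <- "double"
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rows); cn <- readLines(cols)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("mtx annotation files do not match matrix dimensions",
           call. = FALSE)
    if (anyDuplicated(rn)) stop("duplicate gene ids in ", rows, call. = FALSE)
    dimnames(m) <- list(rn, cn)
  }
  as_expression_matrix(m)
}

#' Write an expression matrix as TSV (round-trips with [read_expression()])
#'
#' @param expr genes x samples matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  expr <- as_expression_matrix(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT lines (`name<TAB>description<TAB>gene...`). Orientation
#' dialect: entries named `NAME_UP` and `NAME_DN` are merged into a single
#' signature `NAME` whose `_DN` members carry orientation -1. Entries
#' without the suffix become all-+1 signatures. A gene listed in both halves
#' of the same pair, or an entry with no genes, is an error.
#'
#' The GMT description field is used to carry the signature role when it
#' names one (as written by [write_gmt()]); otherwise `role` applies.
#'
#' @param path GMT file path.
#' @param role fallback role for signatures whose description is not a role.
#' @return named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path, role = "IR-metric") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  known_roles <- c("IR-metric", "pos-salutogenesis", "neg-salutogenesis",
                   "single-gene")
  entries <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT entry '", f[1], "' has no genes", call. = FALSE)
    list(name = f[1], desc = f[2], genes = unique(f[-(1:2)]))
  })
  names(entries) <- vapply(entries, `[[`, "", "name")
  base <- sub("_(UP|DN)$", "", names(entries))
  out <- list()
  for (nm in unique(base)) {
    parts <- entries[base == nm]
    this_role <- if (parts[[1]]$desc %in% known_roles) parts[[1]]$desc else role
    up <- parts[[paste0(nm, "_UP")]]; dn <- parts[[paste0(nm, "_DN")]]
    if (is.null(up) && is.null(dn)) {
      e <- parts[[1]]
      out[[nm]] <- gene_signature(nm, e$genes, 1L, role = this_role)
    } else {
      both <- intersect(up$genes, dn$genes)
      if (length(both))
        stop("gene(s) in both ", nm, "_UP and ", nm, "_DN: ",
             paste(both, collapse = ", "), call. = FALSE)
      genes <- c(up$genes, dn$genes)
      orient <- rep(c(1L, -1L), c(length(up$genes), length(dn$genes)))
      out[[nm]] <- gene_signature(nm, genes, orient, role = this_role)
    }
  }
  out
}

#' Write gene signatures to a GMT file (orientation dialect of [read_gmt()])
#'
#' @param signatures list of [gene_signature()] objects.
#' @param path output path.
#' @export
write_gmt <- function(signatures, path) {
  lines <- character(0)
  for (sig in signatures) {
    up <- sig$genes[sig$orientation == 1L]
    dn <- sig$genes[sig$orientation == -1L]
    if (length(dn) == 0L) {
      lines <- c(lines, paste(c(sig$name, sig$role, up), collapse = "\t"))
    } else {
      lines <- c(lines,
                 paste(c(paste0(sig$name, "_UP"), sig$role, up), collapse = "\t"),
                 paste(c(paste0(sig$name, "_DN"), sig$role, dn), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Write a data.frame as TSV with stable headers and C-locale numbers.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
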
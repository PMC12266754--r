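# Internal helpers: seed management, hashing, validation, logging.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulator internals never perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# 32-bit FNV-1a over a string; arithmetic stays exact in doubles (< 2^53).
fnv1a32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(x))) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

bitwXor_dbl <- function(a, b) {
  # bitwXor works on 32-bit ints; fold the double into range first
  a <- a %% 4294967296
  hi <- a >= 2147483648
  ai <- as.integer(a - ifelse(hi, 4294967296, 0))
  r <- bitwXor(ai, as.integer(b))
  r <- as.numeric(r)
  if (r < 0) r <- r + 4294967296
  r
}

#' Deterministic per-stream seed derived from a global seed
#'
#' Each generator draws from its own substream so partial pipelines are
#' reproducible regardless of which stages run.
#'
#' @param seed global integer seed.
#' @param stream character stream label (e.g. `"expression"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- fnv1a32(paste0(stream, ":", format(seed, scientific = FALSE)))
  as.integer((h %% 2147483646) + 1)
}

# Stable content hash of a config-like list (canonical JSON -> FNV-1a hex).
config_hash <- function(x) {
  j <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                        force = TRUE)
  h <- fnv1a32(as.character(j))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

assert_prob_vector <- function(p, what, tol = 1e-8) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > tol)
    stop(sprintf("%s must be nonnegative and sum to 1 (got sum %.6f)",
                 what, sum(p)), call. = FALSE)
  invisible(p)
}

assert_finite <- function(x, what) {
  if (any(!is.finite(x)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}

ir_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, sprintf(...)))
}

#' IR profile labels in canonical order
#'
#' `H-L` (optimal) through `L-H` (extreme degradation); SAS-1 stratum first,
#' MAS-1 stratum second.
#' @return character vector of the four labels.
#' @export
ir_profile_levels <- function() c("H-L", "H-H", "L-L", "L-H")

#' IHG grade labels in canonical order
#' @return character vector of the eight grade labels.
#' @export
ihg_levels <- function() c("I", "IIa", "IIb", "IIc", "III", "IVa", "IVb", "IVc")
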
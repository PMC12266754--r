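# Shared fixtures, built in code.

# A small, fast configuration for structural tests.
small_cfg <- function(n = 200, seed = 42, ...) {
  sim_config(n_subjects = n, seed = seed, n_noise_genes = 20, ...)
}

# A toy z-scored expression matrix with known values.
toy_zexpr <- function() {
  m <- matrix(c(1, 2, 3,
                2, 2, 2,
                0, 1, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3"), c("s1", "s2", "s3")))
  m
}

# Independent brute-force oracle for trajectory labels: re-states the rules
# as a flat decision list over (baseline, intermediates, final).
oracle_trajectory <- function(profiles) {
  b <- profiles[1]; f <- profiles[length(profiles)]
  if (b != "H-L") return("not-classifiable")
  if (f != "H-L") return("degrader")
  if (any(profiles != "H-L")) return("reconstituter")
  "preserver"
}

# Independent decision-table oracle for IHG grades under given thresholds:
# enumerates the six CD4 bands x two ratio sides as an explicit lookup.
oracle_ihg <- function(cd4, cd8, thr = ihg_thresholds()) {
  stopifnot(cd4 > 0, cd8 > 0)
  band <- findInterval(cd4, c(-Inf, thr$subgrade_bands[2],
                              thr$subgrade_bands[1], thr$cd4_high))
  # band: 1 = c, 2 = b, 3 = a, 4 = high-CD4
  high_ratio <- (cd4 / cd8) >= thr$ratio_cutoff
  lookup <- matrix(c("IVc", "IVb", "IVa", "III",    # ratio below cutoff
                     "IIc", "IIb", "IIa", "I"),     # ratio at/above cutoff
                   nrow = 2, byrow = TRUE)
  lookup[high_ratio + 1L, band]
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration (fixed
# margins; sums tables with point probability <= observed, with the same
# relative tolerance fisher.test uses).
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  obs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
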
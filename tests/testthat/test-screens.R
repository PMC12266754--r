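# BH-FDR, feature screens, dose-response, 2x2 summaries.

test_that("bh_fdr reproduces step-up arithmetic and edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.42), 0.42)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "in \\[0, 1\\]")
  # hand-computed mixed example: sorted p = .005 .03 .04 .8 ->
  # p*m/rank = .02 .06 .0533 .8 -> step-up cummin = .02 .0533 .0533 .8
  expect_equal(bh_fdr(c(0.005, 0.04, 0.03, 0.8)),
               c(0.02, 0.16 / 3, 0.16 / 3, 0.8))
})

test_that("bh_fdr agrees with the reference step-up and is permutation-equivariant", {
  set.seed(71)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  }
  # monotone in p
  p <- sort(runif(30))
  expect_true(all(diff(bh_fdr(p)) >= 0))
})

test_that("screen_features: single feature has q = p; design rank is checked", {
  set.seed(72)
  f <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "f1"))
  rows <- screen_features(f, rnorm(50))
  expect_equal(rows$q, rows$p)
  x <- rnorm(50)
  expect_error(screen_features(f, x, covariates = data.frame(dup = x)),
               "collinear")
  expect_error(screen_features(f, rnorm(10)), "aligned")
})

test_that("linear screen matches per-feature lm and calibrates under the null", {
  set.seed(73)
  n <- 80
  resp <- rnorm(n); age <- runif(n, 40, 90)
  f <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  rows <- screen_features(f, resp, covariates = data.frame(age = age))
  for (j in 1:5) {
    co <- summary(lm(f[, j] ~ resp + age))$coefficients
    expect_equal(rows$beta[j], co["resp", 1], tolerance = 1e-10)
    expect_equal(rows$se[j], co["resp", 2], tolerance = 1e-10)
    expect_equal(rows$p[j], co["resp", 4], tolerance = 1e-10)
  }
  # p uniform across 2000 null features (KS)
  f2 <- matrix(rnorm(200 * 2000), 200)
  rows2 <- screen_features(f2, rnorm(200))
  expect_gt(suppressWarnings(ks.test(rows2$p, "punif"))$p.value, 0.01)
})

test_that("null screens at 1304 features make <= 2 discoveries on average", {
  disc <- vapply(1:20, function(i) {
    cfg <- sim_config(n_subjects = 300, seed = 7000 + i,
                      proteomic_spec = list(n_proteins = 1304L,
                                            n_true_sas = 0L, n_true_mas = 0L,
                                            n_shared = 0L, effect = 0,
                                            noise_sd = 1))
    sas <- with_seed(substream_seed(7000 + i, "s"), rnorm(300))
    mas <- with_seed(substream_seed(7000 + i, "m"), rnorm(300))
    prot <- gen_proteomics(cfg, sas, mas)
    sum(screen_features(prot, sas)$q < 0.05)
  }, numeric(1))
  expect_lte(mean(disc), 2)
})

test_that("planted proteomic structure is recovered with the sets overlapping as planted", {
  cfg <- sim_config(n_subjects = 300, seed = 75,
                    proteomic_spec = list(n_proteins = 300L, n_true_sas = 40L,
                                          n_true_mas = 30L, n_shared = 25L,
                                          effect = 0.8, noise_sd = 1))
  sas <- with_seed(1, rnorm(300)); mas <- with_seed(2, rnorm(300))
  prot <- gen_proteomics(cfg, setNames(sas, 1:300), setNames(mas, 1:300))
  truth <- attr(prot, "truth")
  age <- with_seed(3, runif(300, 40, 90))
  rows_s <- screen_features(prot, sas, covariates = data.frame(age = age))
  rows_m <- screen_features(prot, mas, covariates = data.frame(age = age))
  hit_s <- rows_s$feature[rows_s$q < 0.05]
  hit_m <- rows_m$feature[rows_m$q < 0.05]
  planted_s <- truth$protein[truth$assoc %in% c("SAS", "both")]
  planted_m <- truth$protein[truth$assoc %in% c("MAS", "both")]
  expect_gte(mean(planted_s %in% hit_s), 0.95)  # sensitivity
  expect_gte(mean(planted_m %in% hit_m), 0.95)
  # exact overlap recovery needs a threshold stringent enough to exclude
  # BH-tolerated false discoveries; planted effects sit at q << 1e-10
  ov <- overlap_sets(rows_s$feature[rows_s$q < 1e-3],
                     rows_m$feature[rows_m$q < 1e-3])
  expect_equal(ov$n_shared, 25L)
  expect_equal(sort(ov$shared), sort(truth$protein[truth$assoc == "both"]))
})

test_that("logistic screen recovers a planted log-odds effect", {
  set.seed(76)
  n <- 400
  f <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("hit", "n1", "n2")))
  y <- rbinom(n, 1, plogis(1.2 * f[, "hit"]))
  rows <- screen_features(f, y, family = "logistic")
  expect_lt(rows$q[rows$feature == "hit"], 0.01)
  expect_equal(rows$beta[1], coef(glm(y ~ f[, 1], family = binomial))[2],
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(screen_features(f, rnorm(n), family = "logistic"), "0/1")
})

test_that("overlap_sets does exact set algebra", {
  expect_equal(overlap_sets(c("a", "b"), c("c"))$n_shared, 0L)
  ident <- overlap_sets(c("a", "b"), c("b", "a"))
  expect_equal(ident$n_onlyA, 0L); expect_equal(ident$n_onlyB, 0L)
  ov <- overlap_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$n_shared + ov$n_onlyA, 3L)  # |shared| + |onlyA| = |A|
})

test_that("dose_response bins octiles with ties to the lower bin", {
  set.seed(81)
  n <- 160
  score <- rnorm(n)
  labels <- factor(sample(ir_profile_levels(), n, replace = TRUE),
                   levels = ir_profile_levels())
  dr <- dose_response(score, labels)
  frac <- tapply(dr$prevalence$fraction, dr$prevalence$bin, sum)
  expect_equal(as.numeric(frac), rep(1, 8))  # per-bin fractions sum to 1
  # ties: with many duplicated scores, tied values share the lower bin
  score2 <- rep(c(1, 2), each = n / 2)
  r <- rank(score2, ties.method = "min")
  bin <- floor((r - 1) * 8 / n) + 1
  expect_true(all(bin[score2 == 1] == 1))
  expect_error(dose_response(rnorm(5), labels[1:5]), "at least n_bins")
})

test_that("dose_response slope is calibrated under the null and finds coupling", {
  set.seed(82)
  cover <- vapply(1:100, function(i) {
    score <- rnorm(200)
    labels <- sample(c("H-L", "L-H"), 200, replace = TRUE)
    dr <- dose_response(score, labels, target = "H-L")
    dr$slope_ci[1] <= 0 && 0 <= dr$slope_ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  # planted TCF7 coupling: latent-level recovery at the configured log-odds
  cfg <- sim_config(n_subjects = 10000, seed = 83, n_noise_genes = 0)
  ex <- gen_expression(cfg)
  tr <- attr(ex, "truth")
  dr <- dose_response(ex["TCF7", ],
                      ifelse(tr[["SAS-1"]] > 0, "H", "L"), target = "H")
  expect_gt(cfg$tcf7_coupling, dr$slope_ci[1] - 0.05)
  expect_lt(cfg$tcf7_coupling, dr$slope_ci[2] + 0.05)
})

test_that("summarize_2x2 reproduces the influenza-challenge worked numbers", {
  tab <- rbind(c(10, 7), c(2, 6))  # asymptomatic yes/no by baseline profile
  s <- summarize_2x2(tab)
  expect_equal(round(100 * s$proportions), c(59, 25))
  expect_equal(s$proportions, c(10 / 17, 0.25))
  expect_equal(s$odds_ratio, 60 / 14)
  # symmetric table: OR 1, Fisher p 1
  s2 <- summarize_2x2(rbind(c(5, 5), c(5, 5)))
  expect_equal(s2$odds_ratio, 1)
  expect_equal(s2$fisher_p, 1)
  # Haldane correction only when a zero cell is present
  s3 <- summarize_2x2(rbind(c(5, 0), c(2, 6)))
  expect_equal(s3$odds_ratio, (5.5 * 6.5) / (0.5 * 2.5))
  expect_error(summarize_2x2(rbind(c(-1, 2), c(3, 4))), "nonnegative")
  expect_error(summarize_2x2(matrix(1, 3, 3)), "2x2")
})

test_that("Fisher p matches hypergeometric enumeration on small tables", {
  # all tables with every cell <= 4
  grid <- expand.grid(a = 0:4, b = 0:4, c = 0:4, d = 0:4)
  grid <- grid[rowSums(grid) > 0, ]
  for (i in seq_len(nrow(grid))) {
    tab <- matrix(unlist(grid[i, ]), 2, byrow = TRUE)
    expect_equal(summarize_2x2(tab)$fisher_p, oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
  # random larger tables with grand total <= 30
  set.seed(87)
  for (i in 1:200) {
    tab <- matrix(rmultinom(1, sample(5:30, 1), runif(4, 0.05, 1)), 2)
    expect_equal(summarize_2x2(tab)$fisher_p, oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
})
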
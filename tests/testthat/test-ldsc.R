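# make an ld_score_table directly (for hand-computable regressions)
manual_ld <- function(l, M = length(l)) {
  structure(data.frame(variant_id = paste0("v", seq_along(l)), ldscore = l),
            M = as.integer(M), n_ref = NA_integer_,
            class = c("ld_score_table", "data.frame"))
}

test_that("ld_scores matches the brute-force all-pairs oracle exactly", {
  set.seed(21)
  n_ref <- 120
  # block-diagonal correlation: 10 blocks of 5 correlated variants
  blocks <- lapply(1:10, function(b) {
    f <- rnorm(n_ref)
    t(sapply(1:5, function(i) 0.7 * f + sqrt(1 - 0.49) * rnorm(n_ref)))
  })
  geno <- do.call(rbind, blocks)
  ld <- ld_scores(geno, window = 7)
  expect_equal(ld$ldscore, brute_ld_scores(geno, 7), tolerance = 1e-12)
  expect_equal(attr(ld, "M"), 50)
})

test_that("ld_scores limits: independence gives ~1, perfect LD gives ~2", {
  set.seed(22)
  geno <- matrix(rnorm(40 * 3000), nrow = 40)
  ld <- ld_scores(geno, window = 39)
  # bias-corrected scores center on 1 under independence
  expect_lt(abs(mean(ld$ldscore) - 1), 0.02)

  x <- rnorm(500)
  dup <- rbind(x, x)
  ld2 <- ld_scores(dup, window = 1)
  expect_equal(ld2$ldscore, c(2, 2), tolerance = 1e-10)

  # monomorphic variant warns and gets score 0
  geno_mono <- rbind(rep(1, 100), matrix(rnorm(200), nrow = 2))
  expect_warning(ld3 <- ld_scores(geno_mono, window = 2), "monomorphic")
  expect_equal(ld3$ldscore[1], 0)
})

test_that("ld_scores supports physical-distance windows", {
  set.seed(23)
  geno <- matrix(rnorm(10 * 200), nrow = 10)
  pos <- c(1, 2, 3, 1000, 1001, 1002, 5000, 5001, 5002, 9000) * 100L
  near <- ld_scores(geno, window = 300, units = "bp", pos = pos)
  # oracle: double loop over pairs within 300 bp
  n <- ncol(geno)
  expected <- sapply(seq_len(10), function(j) {
    acc <- 1
    for (k in seq_len(10)) {
      if (k == j || abs(pos[k] - pos[j]) > 300) next
      r <- cor(geno[j, ], geno[k, ])
      acc <- acc + (r^2 - (1 - r^2) / (n - 2))
    }
    max(acc, 0)
  })
  expect_equal(near$ldscore, expected, tolerance = 1e-12)
})

test_that("estimate_h2 reproduces the hand-computed unweighted regression", {
  # 3 points, l = (1,2,3), z^2 = (1.1, 1.2, 1.3), N = 1000, M = 3:
  # slope on l is 0.1, so h2 = slope(on N l/M) = 0.1 * M / N = 3e-4
  ld <- manual_ld(c(1, 2, 3))
  z <- sqrt(c(1.1, 1.2, 1.3))
  est <- estimate_h2(z, rep(1000, 3), ld, n_blocks = 3, weights = "unit")
  expect_equal(est$estimate, 3e-4, tolerance = 1e-10)
  expect_equal(est$intercept, 1.0, tolerance = 1e-10)
  expect_gt(est$se_jackknife, 0)
})

test_that("estimate_h2 input validation", {
  ld <- manual_ld(rep(1, 10))
  expect_error(estimate_h2(rep(0, 10), 100, ld, n_blocks = 11), "blocks")
  expect_error(estimate_h2(c(rep(0, 9), NA), 100, ld, n_blocks = 2),
               "non-finite")
})

test_that("estimate_h2 is unbiased under the null and scales with n", {
  # pure null: z ~ N(0,1), intercept 1, h2 = 0
  arch <- make_architecture("null", M = 5000, N = 50000, seed = 31)
  arch$h2[] <- 0; arch$Sigma_g[] <- 0
  ss <- simulate_sumstats_direct(arch)
  ld <- make_ld_table(arch$M, 31)
  est <- estimate_h2(ss[[1]]$z, ss[[1]]$n, ld, n_blocks = 100)
  expect_lt(abs(est$estimate), 2 * est$se_jackknife)

  # doubling N at fixed E[z^2] halves the estimated h2 exactly
  # (the response is identical; only the regressor rescales)
  ld2 <- make_ld_table(2000, 32)
  set.seed(32)
  z <- rnorm(2000)
  e1 <- estimate_h2(z, rep(20000, 2000), ld2, n_blocks = 50, weights = "unit")
  e2 <- estimate_h2(z, rep(40000, 2000), ld2, n_blocks = 50, weights = "unit")
  expect_equal(e2$estimate, e1$estimate / 2, tolerance = 1e-12)
})

test_that("estimate_gcov: self-covariance equals h2; recovers true r_g", {
  arch <- make_architecture("small", M = 4000, N = 30000, seed = 33)
  ld <- make_ld_table(arch$M, 33)
  ss <- simulate_sumstats_direct(arch, ld)
  z1 <- ss[[1]]$z; n1 <- ss[[1]]$n
  h <- estimate_h2(z1, n1, ld, n_blocks = 100)
  g_self <- estimate_gcov(z1, z1, n1, n1, ld, n_blocks = 100)
  expect_equal(g_self$estimate, h$estimate, tolerance = 1e-12)
  expect_equal(g_self$kind, "h2")

  # true r_g between X1 and X2 is 0.8 * 0.7 = 0.56 on the correlation scale
  z2 <- ss[[2]]$z; n2 <- ss[[2]]$n
  g12 <- estimate_gcov(z1, z2, n1, n2, ld, n_blocks = 100)
  h2b <- estimate_h2(z2, n2, ld, n_blocks = 100)
  rg <- g12$estimate / sqrt(h$estimate * h2b$estimate)
  # delta-method-free check: covariance within 2 jackknife SE of truth
  expect_lt(abs(g12$estimate - arch$Sigma_g[1, 2]), 2 * g12$se_jackknife)
  expect_lt(abs(rg - 0.56), 0.2)
})

test_that("null gcov estimates are calibrated (within 2 SE most of the time)", {
  hits <- 0
  for (s in 1:20) {
    arch <- make_architecture("null", M = 2000, N = 30000, seed = 400 + s)
    ld <- make_ld_table(arch$M, 400 + s)
    ss <- simulate_sumstats_direct(arch, ld)
    g <- estimate_gcov(ss[[1]]$z, ss[[2]]$z, ss[[1]]$n, ss[[2]]$n, ld,
                       n_blocks = 100)
    hits <- hits + (abs(g$estimate) <= 2 * g$se_jackknife)
  }
  expect_gte(hits, 17)  # ~95% nominal; 20 reps
})

test_that("build_S_V assembles S, V with internal consistency", {
  arch <- make_architecture("small", M = 2000, N = 30000, seed = 35)
  ld <- make_ld_table(arch$M, 35)
  pan <- direct_panel(arch, ld)
  sv <- build_S_V(pan, ld, n_blocks = 100)

  expect_equal(sv$S, t(sv$S))
  expect_equal(sv$V, t(sv$V), tolerance = 1e-12)
  # V diagonal equals the squared pairwise jackknife SEs
  expect_equal(unname(diag(sv$V)), unname(sv$pair_se^2), tolerance = 1e-10)
  # recovery within 3 jackknife SE elementwise
  expect_true(all(abs(vech(sv$S) - vech(arch$Sigma_g)) <= 3 * sv$pair_se))

  # duplicated trait: correlation off-diagonal ~= 1
  pan_dup <- pan
  pan_dup$traits <- c("A", "B")
  pan_dup$z <- pan$z[, c(1, 1)]; pan_dup$n <- pan$n[, c(1, 1)]
  colnames(pan_dup$z) <- colnames(pan_dup$n) <- c("A", "B")
  sv_dup <- build_S_V(pan_dup, ld, n_blocks = 100)
  r <- to_correlation(smooth_sv(sv_dup))
  expect_equal(r$S[1, 2], 1, tolerance = 1e-6)

  # trait reordering permutes S consistently
  pan_perm <- pan
  perm <- c(3, 1, 2)
  pan_perm$traits <- pan$traits[perm]
  pan_perm$z <- pan$z[, perm]; pan_perm$n <- pan$n[, perm]
  sv_perm <- build_S_V(pan_perm, ld, n_blocks = 100)
  expect_equal(sv_perm$S, sv$S[perm, perm], tolerance = 1e-12)
})

test_that("to_correlation standardizes S and V by the delta method", {
  s <- matrix(c(0.25, 0.1, 0.1, 0.16), 2, 2)
  sv <- make_sv(s, v = diag(3) * 1e-4, traits = c("a", "b"))
  r <- to_correlation(sv)
  expect_equal(r$S[1, 2], 0.5)
  expect_identical(unname(diag(r$S)), c(1, 1))
  # idempotence
  r2 <- to_correlation(r)
  expect_equal(r2$S, r$S)
  # diagonal moments have zero sampling variance after standardization
  expect_equal(unname(diag(r$V)[c(1, 3)]), c(0, 0))

  # delta-method V agrees with a Monte Carlo transform of vech(S) draws
  set.seed(36)
  vfull <- crossprod(matrix(rnorm(9), 3)) * 1e-4
  sv2 <- make_sv(s, v = vfull, traits = c("a", "b"))
  r3 <- to_correlation(sv2)
  draws <- MASS_free_mvrnorm(20000, vech(s), vfull)
  rg_draws <- draws[, 2] / sqrt(draws[, 1] * draws[, 3])
  expect_equal(r3$V[2, 2], var(rg_draws), tolerance = 0.02)

  expect_error(to_correlation(make_sv(matrix(c(-0.1, 0, 0, 1), 2, 2))),
               "non-positive")
})

test_that("smooth_to_psd truncates eigenvalues and fixes PSD", {
  m_ok <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  expect_equal(unclass(smooth_to_psd(m_ok)), m_ok, ignore_attr = TRUE)
  expect_equal(attr(smooth_to_psd(m_ok), "max_change"), 0)

  m_bad <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_equal(sort(eigen(m_bad)$values), c(-0.2, 2.2))
  sm <- smooth_to_psd(m_bad)
  ev <- eigen(sm, symmetric = TRUE)$values
  expect_gte(min(ev), 0)
  expect_equal(sm, t(sm))

  # property: random indefinite 6x6 inputs come out PSD above the floor
  set.seed(37)
  for (i in 1:20) {
    a <- matrix(rnorm(36), 6); a <- (a + t(a)) / 2
    sm <- smooth_to_psd(a)
    ev <- eigen(sm, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-12)
  }
})

test_that("LD scores and S/V round-trip through their text formats", {
  arch <- make_architecture("small", M = 500, N = 10000, seed = 38)
  ld <- make_ld_table(arch$M, 38)
  p <- tempfile(fileext = ".tsv")
  write_ld_scores(ld, p)
  back <- read_ld_scores(p)
  expect_equal(back$ldscore, ld$ldscore)
  expect_equal(attr(back, "M"), attr(ld, "M"))

  pan <- direct_panel(arch, ld)
  sv <- build_S_V(pan, ld, n_blocks = 50)
  prefix <- tempfile()
  write_sv(sv, prefix)
  back_sv <- read_sv(prefix)
  expect_equal(back_sv$S, sv$S, tolerance = 1e-12)
  expect_equal(unname(back_sv$V), unname(sv$V), tolerance = 1e-12)
})
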
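triad_S <- matrix(c(1, .5, .4,
                    .5, 1, .2,
                    .4, .2, 1), 3, 3, dimnames = list(c("a", "b", "c"),
                                                      c("a", "b", "c")))

test_that("saturated model reproduces S exactly with chisq = df = 0", {
  sv <- make_sv(triad_S)
  fit <- fit_dwls(sv, saturated_spec(c("a", "b", "c")))
  expect_true(fit$converged)
  expect_equal(fit$df, 0)
  expect_equal(fit$chisq, 0)
  expect_equal(fit$implied, unname(triad_S), tolerance = 1e-8)
  idx <- fit_indices(fit, sv)
  expect_equal(idx$cfi, 1)
  expect_equal(idx$srmr, 0, tolerance = 1e-7)
})

test_that("df = 0 one-factor solution matches the triad closed form to 1e-6", {
  sv <- make_sv(triad_S, v = diag(6) * c(1, 2, 3, 1, 2, 1) * 1e-3)
  fit <- suppressWarnings(fit_dwls(sv, parse_model("F =~ a + b + c")))
  # closed form: lambda_a = sqrt(s_ab s_ac / s_bc), etc.
  l_a <- sqrt(.5 * .4 / .2)
  expect_equal(unname(fit$estimates["F=~a"]), l_a, tolerance = 1e-6)
  expect_equal(unname(fit$estimates["F=~b"]), .5 / l_a, tolerance = 1e-6)
  expect_equal(unname(fit$estimates["F=~c"]), .4 / l_a, tolerance = 1e-6)
  expect_equal(fit$chisq, 0, tolerance = 1e-10)
})

test_that("grid-search oracle bounds the optimizer on a 2-parameter model", {
  # loadings fixed at (1, .8, .6); free: factor variance psi, residual ra.
  # implied: diag = (psi + ra, .64 psi + .2, .36 psi + .3),
  #          off  = (.8 psi, .6 psi, .48 psi)
  txt <- "F =~ 1*a + 0.8*b + 0.6*c
          b ~~ 0.2*b \n c ~~ 0.3*c"
  spec <- parse_model(txt, identification = "marker_loading")
  expect_equal(n_free_params(spec), 2)
  sv <- make_sv(triad_S, v = diag(6) * 1e-2)
  fit <- fit_dwls(sv, spec)

  s_vec <- vech(triad_S)
  w <- rep(1 / 1e-2, 6)
  obj <- function(psi, ra) {
    sig <- c(psi + ra, .8 * psi, .6 * psi, .64 * psi + .2, .48 * psi,
             .36 * psi + .3)
    sum(w * (s_vec - sig)^2)
  }
  grid <- expand.grid(psi = seq(0, 1, by = 1e-3), ra = seq(0, 1, by = 1e-3))
  vals <- obj(grid$psi, grid$ra)
  expect_gte(min(vals), fit$objective - 1e-6)
})

test_that("DWLS objective never exceeds the value at any start point", {
  arch <- make_architecture("an_impulsivity", M = 4000, N = 50000, seed = 61)
  ld <- make_ld_table(arch$M, 61)
  sv <- smooth_sv(build_S_V(direct_panel(arch, ld), ld, n_blocks = 100))
  spec <- correlated_factors_model()
  fit <- fit_dwls(sv, spec, seed = 2)
  s <- sv$S[spec$observed, spec$observed]
  th0 <- gencovsem:::start_values(spec, s)
  # recompute the DWLS objective at the heuristic start
  skel <- gencovsem:::ram_skeleton(spec)
  sel_sv <- sv; # same trait order as spec here
  idx <- vech_index(length(spec$observed))
  vsel <- sv$V  # trait order identical, so V aligns with vech order
  w <- 1 / diag(vsel)
  sig0 <- vech(implied_cov(spec, th0))
  obj0 <- sum(w * (vech(s) - sig0)^2)
  expect_lte(fit$objective, obj0 + 1e-9)
})

test_that("mean-corrected chi-square is calibrated under a true model", {
  # fit the generating model to many simulated S,V; chisq mean ~ df
  chis <- numeric(15)
  for (s in seq_along(chis)) {
    arch <- make_architecture("small", M = 2000, N = 30000, seed = 600 + s)
    ld <- make_ld_table(arch$M, 600 + s)
    sv <- smooth_sv(build_S_V(direct_panel(arch, ld), ld, n_blocks = 100))
    fit <- fit_dwls(sv, parse_model("F =~ X1 + X2 + X3"), seed = s)
    chis[s] <- fit$chisq
  }
  df <- 0  # one-factor on 3 indicators is just-identified
  expect_true(all(chis < 1e-8))

  # over-identified case: 4 traits, one factor (df = 2)
  chis4 <- numeric(15)
  for (s in seq_along(chis4)) {
    arch <- make_architecture("null", M = 2000, N = 30000, seed = 700 + s)
    # give the null traits a common factor structure
    lam <- c(0.6, 0.5, 0.55, 0.45)
    std <- tcrossprod(lam); diag(std) <- 1
    h2 <- c(0.2, 0.25, 0.3, 0.22)
    arch$Sigma_g <- sqrt(outer(h2, h2)) * std
    dimnames(arch$Sigma_g) <- list(arch$traits, arch$traits)
    arch$h2 <- setNames(h2, arch$traits)
    ld <- make_ld_table(arch$M, 700 + s)
    sv <- smooth_sv(build_S_V(direct_panel(arch, ld), ld, n_blocks = 100))
    fit <- fit_dwls(sv, parse_model(paste("F =~", paste(arch$traits, collapse = " + "))),
                    seed = s)
    chis4[s] <- fit$chisq
  }
  # E[chisq] = df = 2; mean over 15 replicates within a generous band
  expect_gt(mean(chis4), 2 * 0.35)
  expect_lt(mean(chis4), 2 * 2.5)
})

test_that("Heywood cases warn but do not error", {
  s <- matrix(c(1, .9, .9,
                .9, 1, .3,
                .9, .3, 1), 3, 3, dimnames = list(c("a", "b", "c"),
                                                  c("a", "b", "c")))
  expect_warning(fit_dwls(make_sv(s), parse_model("F =~ a + b + c")),
                 "Heywood")
})

test_that("fit_indices: SRMR hand oracle and CFI ordering", {
  # 2 observed, fully fixed model leaving residuals (0.1, 0, -0.1) on the
  # correlation scale -> SRMR = sqrt((0.01 + 0 + 0.01)/3)
  s <- diag(2); dimnames(s) <- list(c("a", "b"), c("a", "b"))
  spec_fixed <- parse_model("a ~~ 0.9*a\nb ~~ 1.1*b\na ~~ 0*b")
  sv <- make_sv(s)
  fit <- fit_dwls(sv, spec_fixed)
  expect_equal(fit$df, 3)
  idx <- fit_indices(fit, sv, spec_fixed)
  expect_equal(idx$srmr, sqrt(0.02 / 3), tolerance = 1e-10)

  # a badly misspecified model has lower CFI than the saturated one
  s2 <- matrix(.6, 3, 3); diag(s2) <- 1
  dimnames(s2) <- list(c("a", "b", "c"), c("a", "b", "c"))
  sv2 <- make_sv(s2, v = diag(6) * 1e-4)
  bad <- parse_model("a ~~ 1*a\nb ~~ 1*b\nc ~~ 1*c\na ~~ 0*b\na ~~ 0*c\nb ~~ 0*c")
  fit_bad <- fit_dwls(sv2, bad)
  idx_bad <- fit_indices(fit_bad, sv2, bad)
  expect_lt(idx_bad$cfi, 0.05)   # the independence model IS this model
  expect_gt(idx_bad$srmr, 0.3)

  # AIC = chisq + 2q
  expect_equal(idx$aic, fit$chisq + 0)
})

test_that("standardize_solution rescales to the correlation metric", {
  # covariance 0.1 between variances 0.25 and 0.16 -> correlation 0.5
  s <- matrix(c(0.25, 0.1, 0.1, 0.16), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  sv <- make_sv(s)
  fit <- fit_dwls(sv, saturated_spec(c("x", "y")))
  std <- standardize_solution(fit)
  expect_equal(unname(std$estimates["x~~y"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(std$estimates["x~~x"]), 1, tolerance = 1e-6)

  # already standardized input: estimates unchanged
  s1 <- matrix(c(1, .3, .3, 1), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  fit1 <- fit_dwls(make_sv(s1), saturated_spec(c("x", "y")))
  std1 <- standardize_solution(fit1)
  expect_equal(std1$estimates, fit1$estimates, tolerance = 1e-6)

  # property: standardized factor correlations stay in [-1, 1]
  for (s_i in 1:5) {
    arch <- make_architecture("small", M = 1500, N = 20000, seed = 800 + s_i)
    ld <- make_ld_table(arch$M, 800 + s_i)
    sv_i <- smooth_sv(build_S_V(direct_panel(arch, ld), ld, n_blocks = 75))
    fit_i <- suppressWarnings(fit_dwls(sv_i, parse_model("F =~ X1 + X2 + X3"),
                                       seed = s_i))
    std_i <- suppressWarnings(standardize_solution(fit_i))
    lam <- std_i$estimates[grep("=~", names(std_i$estimates))]
    expect_true(all(abs(lam) <= 1 + 1e-6))
  }
})

test_that("sandwich SEs match a jackknife-free Monte Carlo check", {
  # simulate many (S, V), fit, and compare empirical sd of estimates with
  # the mean sandwich SE (ratio within a loose band)
  ests <- ses <- numeric(25)
  for (s in 1:25) {
    arch <- make_architecture("small", M = 1500, N = 30000, seed = 900 + s)
    ld <- make_ld_table(arch$M, 900 + s)
    sv <- smooth_sv(build_S_V(direct_panel(arch, ld), ld, n_blocks = 75))
    fit <- suppressWarnings(fit_dwls(sv, parse_model("F =~ X1 + X2 + X3"),
                                     seed = s))
    ests[s] <- fit$estimates["F=~X1"]
    ses[s] <- fit$se["F=~X1"]
  }
  ratio <- sd(ests) / mean(ses)
  expect_gt(ratio, 0.55)
  expect_lt(ratio, 1.8)
})
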
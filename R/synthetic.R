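# Simulation of GWAS summary statistics under a known factor-structured
# genetic architecture, in two modes:
#  - direct: draw per-variant z-score vectors from the multivariate
#    LD-score model, Cov[z_aj, z_bj] = sqrt(N_a N_b) rho_g,ab l_j / M +
#    overlap_ab rho_pheno,ab / sqrt(N_a N_b), Var[z_aj] = 1 + N_a h2_a l_j/M.
#  - forward: simulate block-correlated genotypes, multivariate polygenic
#    effects with Cov = Sigma_g / M, phenotypes, and per-variant regression
#    z-scores, exercising the reader and LD-score stages end to end.

#' Construct a true genetic architecture
#'
#' Presets:
#' \describe{
#'   \item{an_impulsivity}{14 traits (six common-impulsivity indicators, four
#'     SUDs, DD/SS/PERSEV/AN), 3 latent factors with the urgency factor
#'     orthogonal to common impulsivity, a negative AN-DD and AN-PERSEV
#'     genetic covariance, full sample overlap among the nine
#'     questionnaire traits.}
#'   \item{small}{3 traits loading on one factor; fast smoke-test scale.}
#'   \item{null}{4 independent traits (diagonal Sigma_g), no overlap.}
#' }
#'
#' @param preset one of "an_impulsivity", "small", "null", "single" (one trait
#'   with h2 = 0.5, for forward-mode recovery checks)
#' @param M causal variant count
#' @param N per-trait sample size (scalar or per-trait vector)
#' @param seed integer seed stored in the architecture and used by the
#'   simulators
#' @return a \code{true_architecture} list: traits, Lambda (std-scale
#'   loadings), Psi (latent/single correlation matrix), h2, Sigma_g
#'   (covariance-scale genetic covariance), N, overlap, rho_pheno, M, seed,
#'   and \code{true_partable} (the covariance-scale values of the free
#'   parameters of the matching correlated-factor model, an_impulsivity only)
#' @export
make_architecture <- function(preset = c("an_impulsivity", "small", "null", "single"),
                              M = 10000L, N = 50000, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "single") {
    sigma <- matrix(0.5, 1, 1, dimnames = list("T1", "T1"))
    arch <- list(preset = preset, traits = "T1", K = 1L,
                 Lambda = NULL, Psi = NULL, h2 = c(T1 = 0.5),
                 Sigma_g = sigma,
                 N = setNames(rep_len(N, 1), "T1"),
                 overlap = matrix(N, 1, 1, dimnames = list("T1", "T1")),
                 rho_pheno = matrix(1, 1, 1, dimnames = list("T1", "T1")),
                 M = as.integer(M), seed = as.integer(seed))
    class(arch) <- "true_architecture"
    return(arch)
  }
  if (preset == "null") {
    traits <- paste0("T", 1:4)
    h2 <- rep(0.1, 4)
    sigma <- diag(h2)
    dimnames(sigma) <- list(traits, traits)
    arch <- list(preset = preset, traits = traits, K = 4L,
                 Lambda = NULL, Psi = NULL,
                 h2 = setNames(h2, traits),
                 Sigma_g = sigma,
                 N = setNames(rep_len(N, 4), traits),
                 overlap = matrix(0, 4, 4, dimnames = list(traits, traits)),
                 rho_pheno = matrix(0, 4, 4, dimnames = list(traits, traits)),
                 M = as.integer(M), seed = as.integer(seed))
    class(arch) <- "true_architecture"
    return(arch)
  }
  if (preset == "small") {
    traits <- c("X1", "X2", "X3")
    lam <- c(0.8, 0.7, 0.6)
    h2 <- setNames(c(0.3, 0.25, 0.2), traits)
    std <- tcrossprod(lam) ; diag(std) <- 1
    sigma <- sqrt(outer(h2, h2)) * std
    dimnames(sigma) <- list(traits, traits)
    arch <- list(preset = preset, traits = traits, K = 3L,
                 Lambda = matrix(lam, 3, 1, dimnames = list(traits, "F")),
                 Psi = matrix(1, 1, 1, dimnames = list("F", "F")),
                 h2 = h2, Sigma_g = sigma,
                 N = setNames(rep_len(N, 3), traits),
                 overlap = matrix(0, 3, 3, dimnames = list(traits, traits)),
                 rho_pheno = matrix(0, 3, 3, dimnames = list(traits, traits)),
                 M = as.integer(M), seed = as.integer(seed))
    class(arch) <- "true_architecture"
    return(arch)
  }

  # ---- an_impulsivity -------------------------------------------------------
  ind <- c("NU", "PU", "PREMED", "ATT", "MOT", "NONPLAN")
  sud <- c("PAU", "CUD", "OUD", "TUD")
  singles <- c("DD", "SS", "PERSEV")
  traits <- c(ind, sud, singles, "AN")
  k <- length(traits)

  # standardized (genetic-correlation scale) loadings
  lam_ci  <- setNames(c(0.80, 0.78, 0.60, 0.70, 0.65, 0.72), ind)
  lam_urg <- setNames(c(0.45, 0.45), c("NU", "PU"))
  lam_sud <- setNames(c(0.75, 0.70, 0.65, 0.60), sud)

  ents <- c("CI", "URG", "SUD", singles, "AN")
  psi <- diag(7)
  dimnames(psi) <- list(ents, ents)
  set_psi <- function(a, b, v) { psi[a, b] <<- v; psi[b, a] <<- v }
  set_psi("CI", "SUD", 0.55); set_psi("CI", "DD", 0.30)
  set_psi("CI", "SS", 0.40); set_psi("CI", "PERSEV", 0.35)
  set_psi("CI", "AN", -0.07)
  set_psi("URG", "SUD", 0.25); set_psi("URG", "DD", 0.10)
  set_psi("URG", "SS", 0.10); set_psi("URG", "PERSEV", 0.10)
  set_psi("URG", "AN", 0.14)
  set_psi("SUD", "DD", 0.30); set_psi("SUD", "SS", 0.25)
  set_psi("SUD", "PERSEV", 0.10); set_psi("SUD", "AN", 0.07)
  set_psi("DD", "SS", 0.10); set_psi("DD", "PERSEV", 0.10)
  set_psi("DD", "AN", -0.19)
  set_psi("SS", "PERSEV", 0.05); set_psi("SS", "AN", -0.07)
  set_psi("PERSEV", "AN", -0.15)
  stopifnot(min(eigen(psi, symmetric = TRUE, only.values = TRUE)$values) > 0)

  lambda <- matrix(0, k, 3, dimnames = list(traits, c("CI", "URG", "SUD")))
  lambda[ind, "CI"] <- lam_ci
  lambda[names(lam_urg), "URG"] <- lam_urg
  lambda[sud, "SUD"] <- lam_sud

  # full std-scale loading matrix including identity rows for singles/AN
  lam_full <- cbind(lambda, matrix(0, k, 4, dimnames = list(traits, c(singles, "AN"))))
  for (v in c(singles, "AN")) lam_full[v, v] <- 1
  theta_std <- 1 - rowSums((lam_full %*% psi) * lam_full)
  theta_std[c(singles, "AN")] <- 0
  stopifnot(all(theta_std > -1e-12))
  theta_std <- pmax(theta_std, 0)
  std <- lam_full %*% psi %*% t(lam_full) + diag(theta_std)
  stopifnot(max(abs(diag(std) - 1)) < 1e-10)

  h2 <- setNames(c(0.08, 0.08, 0.06, 0.07, 0.07, 0.07,   # UPPS-P / BIS
                   0.07, 0.08, 0.09, 0.08,               # SUDs
                   0.10, 0.08, 0.06,                     # DD, SS, PERSEV
                   0.12), traits)                        # AN (effective N scale)
  sigma <- sqrt(outer(h2, h2)) * std
  dimnames(sigma) <- list(traits, traits)

  nvec <- setNames(rep_len(N, k), traits)
  # the nine questionnaire traits share one cohort
  cohort <- c(ind, singles)
  overlap <- matrix(0, k, k, dimnames = list(traits, traits))
  overlap[cohort, cohort] <- outer(nvec[cohort], nvec[cohort], pmin)
  diag(overlap) <- nvec
  # modest phenotypic correlation within the shared cohort
  rho_ph <- matrix(0, k, k, dimnames = list(traits, traits))
  rho_ph[cohort, cohort] <- 0.3 * std[cohort, cohort]
  diag(rho_ph) <- 1

  # covariance-scale true values of the correlated-factor model parameters
  tp <- list()
  for (v in ind) tp[[paste0("CI=~", v)]] <- unname(sqrt(h2[v]) * lam_ci[v])
  for (v in names(lam_urg)) tp[[paste0("URG=~", v)]] <- unname(sqrt(h2[v]) * lam_urg[v])
  for (v in sud) tp[[paste0("SUD=~", v)]] <- unname(sqrt(h2[v]) * lam_sud[v])
  for (v in c(ind, sud)) tp[[paste0(v, "~~", v)]] <- unname(h2[v] * theta_std[v])
  for (v in c(singles, "AN")) tp[[paste0(v, "~~", v)]] <- unname(h2[v])
  ent_scale <- setNames(c(1, 1, 1, sqrt(h2[singles]), sqrt(h2["AN"])), ents)
  for (i in seq_along(ents)) for (j in seq_along(ents)) {
    if (i >= j) next
    a <- ents[i]; b <- ents[j]
    if ((a == "CI" && b == "URG") || (a == "URG" && b == "CI")) next
    key <- paste0(min(a, b), "~~", max(a, b))
    tp[[key]] <- unname(psi[a, b] * ent_scale[a] * ent_scale[b])
  }

  arch <- list(preset = preset, traits = traits, K = k,
               Lambda = lambda, Psi = psi,
               h2 = h2, Sigma_g = sigma,
               N = nvec, overlap = overlap, rho_pheno = rho_ph,
               M = as.integer(M), seed = as.integer(seed),
               true_partable = unlist(tp))
  class(arch) <- "true_architecture"
  arch
}

#' @export
print.true_architecture <- function(x, ...) {
  cat("true_architecture [", x$preset, "]: K =", x$K, ", M =", x$M,
      ", seed =", x$seed, "\n")
  invisible(x)
}

#' Synthetic LD-score table
#'
#' Draws desk-scale LD scores l_j = 1 + Gamma(shape, scale) so the direct
#' simulator and the estimators share a known LD structure without a
#' reference panel.
#'
#' @param m number of variants
#' @param seed RNG seed
#' @param shape,scale Gamma parameters of the excess LD score
#' @export
make_ld_table <- function(m, seed = 1L, shape = 3, scale = 10) {
  set.seed(seed)
  structure(data.frame(variant_id = sprintf("rs%06d", seq_len(m)),
                       ldscore = 1 + rgamma(m, shape = shape, scale = scale),
                       stringsAsFactors = FALSE),
            M = as.integer(m), n_ref = NA_integer_,
            class = c("ld_score_table", "data.frame"))
}

# non-ambiguous allele pairs for synthetic variant maps
NONAMBIG_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                         ncol = 2, byrow = TRUE)

synthetic_variant_map <- function(m) {
  pick <- sample.int(4, m, replace = TRUE)
  data.frame(variant_id = sprintf("rs%06d", seq_len(m)),
             chrom = "1", pos = seq_len(m) * 1000L,
             allele_effect = NONAMBIG_PAIRS[pick, 1],
             allele_other = NONAMBIG_PAIRS[pick, 2],
             freq = runif(m, 0.05, 0.5),
             stringsAsFactors = FALSE)
}

#' Simulate summary statistics directly from the LD-score model
#'
#' Per-variant z vectors are drawn as z_j = L_E u + sqrt(l_j) L_G v with
#' independent standard-normal u, v, where E = I + overlap-intercept matrix
#' and G = diag(sqrt(N)) Sigma_g diag(sqrt(N)) / M, so that the per-variant
#' covariance is exactly E + l_j G (the bivariate LD-score model). Both E
#' and G must be PSD; the per-variant covariance then is too.
#'
#' @param arch a \code{true_architecture}
#' @param ld an \code{ld_score_table} with at least \code{arch$M} rows
#' @return named list of \code{sumstats_table}, one per trait, on a shared
#'   variant index; byte-reproducible given \code{arch$seed}
#' @export
simulate_sumstats_direct <- function(arch, ld = make_ld_table(arch$M, arch$seed)) {
  stopifnot(inherits(arch, "true_architecture"))
  m <- arch$M
  if (nrow(ld) < m) stop("ld table covers fewer variants than arch$M")
  l <- ld$ldscore[seq_len(m)]
  k <- arch$K
  nv <- arch$N
  g <- sqrt(outer(nv, nv)) * arch$Sigma_g / m
  e <- arch$overlap * arch$rho_pheno / sqrt(outer(nv, nv))
  diag(e) <- 1
  le <- tryCatch(t(chol(e)), error = function(err)
    stop("overlap-intercept matrix E is not positive definite"))
  eg <- eigen(g, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values))
    stop("per-variant covariance component G is not PSD")
  lg <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), k)

  set.seed(arch$seed)
  map <- synthetic_variant_map(m)
  u <- matrix(rnorm(m * k), m, k)
  v <- matrix(rnorm(m * k), m, k)
  z <- u %*% t(le) + (sqrt(l) * v) %*% t(lg)
  colnames(z) <- arch$traits

  out <- lapply(seq_len(k), function(j) {
    df <- data.frame(variant_id = map$variant_id, chrom = map$chrom,
                     pos = map$pos, allele_effect = map$allele_effect,
                     allele_other = map$allele_other,
                     z = z[, j], n = unname(nv[j]),
                     freq_effect = map$freq,
                     pvalue = 2 * pnorm(-abs(z[, j])),
                     stringsAsFactors = FALSE)
    structure(df, trait_label = arch$traits[j],
              class = c("sumstats_table", "data.frame"))
  })
  names(out) <- arch$traits
  out
}

# block-AR(1) latent haplotype draw -> allele indicator given maf
sim_haplotype_block <- function(n, m_block, rho, maf) {
  z <- matrix(rnorm(n * m_block), n, m_block)
  if (rho > 0 && m_block > 1) {
    for (j in 2:m_block)
      z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  }
  # allele = 1 when latent below the maf quantile
  sweep(z, 2, qnorm(maf), "<") * 1L
}

sim_genotypes <- function(n, m, block_size, rho, maf) {
  geno <- matrix(0L, m, n)
  starts <- seq(1L, m, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, m)
    mb <- e - s + 1L
    h1 <- sim_haplotype_block(n, mb, rho, maf[s:e])
    h2 <- sim_haplotype_block(n, mb, rho, maf[s:e])
    geno[s:e, ] <- t(h1 + h2)
  }
  geno
}

#' Forward simulation: genotypes, phenotypes, and summary statistics
#'
#' Simulates a reference dosage panel and GWAS cohorts with
#' block-autocorrelated genotypes, draws per-variant multivariate effects
#' with Cov = Sigma_g / M, builds phenotypes (continuous, or case-control
#' by liability threshold), and computes per-trait single-variant
#' regression z-scores. Traits whose pairwise overlap equals min(N) share
#' one cohort; all other pairs use disjoint cohorts (fractional overlap is
#' not supported in forward mode).
#'
#' @param arch a \code{true_architecture}
#' @param n_ref reference-panel size (>= 50)
#' @param ld_block_size variants per LD block
#' @param ld_rho within-block AR(1) haplotype correlation in \[0, 1)
#' @param prevalence named vector of case prevalences for case-control
#'   traits (others continuous); z then uses the point-biserial correlation
#'   with the user-supplied effective N
#' @return list with \code{panel} (dosage matrix + map), \code{ld}
#'   (LD scores from the panel), and \code{sumstats} (list of tables)
#' @export
simulate_individual <- function(arch, n_ref = 500, ld_block_size = 20,
                                ld_rho = 0.5, prevalence = NULL) {
  stopifnot(inherits(arch, "true_architecture"),
            ld_rho >= 0, ld_rho < 1, n_ref >= 50)
  m <- arch$M; k <- arch$K
  if (m %% ld_block_size != 0)
    message("M not divisible by ld_block_size; last block shortened")
  set.seed(arch$seed)
  map <- synthetic_variant_map(m)
  maf <- map$freq

  # cohort groups from the overlap matrix (full overlap = shared cohort)
  full <- arch$overlap >= outer(arch$N, arch$N, pmin) - 0.5
  diag(full) <- TRUE
  grp <- rep(NA_integer_, k)
  gcur <- 0L
  for (j in seq_len(k)) {
    if (is.na(grp[j])) { gcur <- gcur + 1L; grp[j] <- gcur }
    grp[full[j, ] & is.na(grp)] <- grp[j]
  }

  # per-variant multivariate effects, Cov = Sigma_g / M (standardized scale)
  es <- eigen(arch$Sigma_g, symmetric = TRUE)
  lb <- es$vectors %*% diag(sqrt(pmax(es$values, 0) / m), k)
  beta <- matrix(rnorm(m * k), m, k) %*% t(lb)   # m x k

  # reference panel
  ref <- sim_genotypes(n_ref, m, ld_block_size, ld_rho, maf)

  sumstats <- vector("list", k)
  for (gid in seq_len(gcur)) {
    members <- which(grp == gid)
    n_g <- max(arch$N[members])
    geno <- sim_genotypes(n_g, m, ld_block_size, ld_rho, maf)
    p_hat <- rowMeans(geno) / 2
    sdv <- sqrt(2 * p_hat * (1 - p_hat))
    sdv[sdv == 0] <- Inf
    xs <- (geno - 2 * p_hat) / sdv        # variants x samples, standardized

    kg <- length(members)
    gvals <- crossprod(xs, beta[, members, drop = FALSE])  # n_g x kg
    # residuals: phenotypic residual correlation within the group
    rph <- arch$rho_pheno[members, members, drop = FALSE]
    gcov <- arch$Sigma_g[members, members, drop = FALSE]
    ecov <- rph - gcov
    diag(ecov) <- 1 - diag(gcov)
    ee <- eigen((ecov + t(ecov)) / 2, symmetric = TRUE)
    lec <- ee$vectors %*% diag(sqrt(pmax(ee$values, 1e-8)), kg)
    eps <- matrix(rnorm(n_g * kg), n_g, kg) %*% t(lec)
    y <- gvals + eps

    for (jj in seq_len(kg)) {
      tr <- arch$traits[members[jj]]
      n_t <- arch$N[members[jj]]
      yj <- y[seq_len(n_t), jj]
      xj <- xs[, seq_len(n_t), drop = FALSE]
      prev <- if (!is.null(prevalence) && tr %in% names(prevalence))
        prevalence[[tr]] else NA
      if (!is.na(prev)) {
        yj <- as.numeric(yj > stats::quantile(yj, 1 - prev))
      }
      yc <- yj - mean(yj)
      num <- as.numeric(xj %*% yc)
      den <- sqrt(rowSums(xj^2) * sum(yc^2))
      r <- ifelse(den > 0, num / den, 0)
      zj <- sqrt(n_t) * r
      df <- data.frame(variant_id = map$variant_id, chrom = map$chrom,
                       pos = map$pos, allele_effect = map$allele_effect,
                       allele_other = map$allele_other,
                       z = zj, n = unname(n_t), freq_effect = p_hat,
                       pvalue = 2 * pnorm(-abs(zj)),
                       stringsAsFactors = FALSE)
      sumstats[[members[jj]]] <- structure(
        df, trait_label = tr, class = c("sumstats_table", "data.frame"))
    }
    rm(geno, xs, gvals, eps, y)
  }
  names(sumstats) <- arch$traits

  ld <- ld_scores(ref, window = 2L * ld_block_size,
                  variant_id = map$variant_id)
  list(panel = list(dosage = ref, map = map), ld = ld, sumstats = sumstats)
}

#' Serialize an architecture as JSON for provenance
#' @param arch a \code{true_architecture}
#' @param path output path
#' @export
write_architecture <- function(arch, path) {
  write_json_file(list(preset = arch$preset, traits = as.list(arch$traits),
                       K = arch$K, M = arch$M, seed = arch$seed,
                       h2 = as.list(arch$h2), N = as.list(arch$N),
                       Sigma_g = apply(arch$Sigma_g, 1, as.list)),
                  path)
}
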
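# LD-score regression: LD scores from a reference dosage panel,
# heritability and genetic-covariance estimation, and assembly of the
# multi-trait genetic covariance matrix S with its block-jackknife sampling
# covariance V.
#
# Regression parameterization. For trait a, E[z_aj^2] = 1 + N_a*c + (N_a
# h2_a / M) l_j; for a pair (a,b), E[z_aj z_bj] = sqrt(N_a N_b) rho_g l_j /
# M + rho N_s / sqrt(N_a N_b). Both are fit as a straight line of the
# response on x_j = (n_j-scaled) l_j / M so that the slope IS h2 (resp.
# rho_g) and the intercept absorbs confounding / sample overlap.

#' Compute LD scores from a reference dosage panel
#'
#' The LD score of variant j is the sum of squared correlations with all
#' variants inside the window (including its own r^2 = 1 term), each
#' corrected for reference-panel sampling noise by
#' r2_adj = r2 - (1 - r2) / (n_ref - 2). Negative totals are truncated at 0.
#'
#' @param genotypes numeric matrix, variants x samples (dosages)
#' @param window window half-width; a variant count by default, or a
#'   physical distance in base pairs when \code{units = "bp"} (requires
#'   \code{pos})
#' @param units \code{"variants"} or \code{"bp"}
#' @param pos integer base-pair positions, needed for \code{units = "bp"}
#' @param variant_id optional ids (default V1..Vm)
#' @return an \code{ld_score_table}: data.frame(variant_id, ldscore) with
#'   attributes \code{M} (number of variants) and \code{n_ref}
#' @export
ld_scores <- function(genotypes, window = 100L, units = c("variants", "bp"),
                      pos = NULL, variant_id = NULL) {
  units <- match.arg(units)
  stopifnot(is.matrix(genotypes))
  m <- nrow(genotypes); n_ref <- ncol(genotypes)
  if (n_ref < 3) stop("reference panel needs n_ref >= 3")
  if (units == "bp" && is.null(pos)) stop("units='bp' requires pos")
  if (is.null(variant_id)) variant_id <- paste0("V", seq_len(m))

  sds <- apply(genotypes, 1, stats::sd)
  mono <- sds == 0 | !is.finite(sds)
  if (any(mono))
    warning(sum(mono), " monomorphic variant(s); their correlations set to 0")
  xs <- genotypes
  xs[!mono, ] <- (genotypes[!mono, , drop = FALSE] -
                    rowMeans(genotypes[!mono, , drop = FALSE])) / sds[!mono]
  xs[mono, ] <- 0
  xs <- xs / sqrt(n_ref - 1)  # so tcrossprod gives correlations

  lo <- hi <- integer(m)
  if (units == "variants") {
    lo <- pmax(seq_len(m) - window, 1L)
    hi <- pmin(seq_len(m) + window, m)
  } else {
    ord <- order(pos)
    stopifnot(!is.unsorted(pos))  # keep it simple: require sorted positions
    lo <- findInterval(pos - window, pos) + 1L
    lo <- pmin(lo, seq_len(m))
    hi <- findInterval(pos + window, pos)
  }

  l <- numeric(m)
  adj <- function(r2) r2 - (1 - r2) / (n_ref - 2)
  # process target variants in chunks; one crossprod per chunk
  chunk <- 512L
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    rng <- seq.int(min(lo[s:e]), max(hi[s:e]))
    r <- xs[s:e, , drop = FALSE] %*% t(xs[rng, , drop = FALSE])
    r2 <- adj(r * r)
    for (jj in s:e) {
      cols <- (lo[jj]:hi[jj]) - rng[1L] + 1L
      self <- jj - rng[1L] + 1L
      l[jj] <- sum(r2[jj - s + 1L, cols]) - r2[jj - s + 1L, self] +
        (if (mono[jj]) 0 else 1)  # own term exactly 1
    }
  }
  l[mono] <- 0
  l <- pmax(l, 0)
  structure(data.frame(variant_id = variant_id, ldscore = l,
                       stringsAsFactors = FALSE),
            M = m, n_ref = n_ref,
            class = c("ld_score_table", "data.frame"))
}

#' Write / read LD scores as delimited text
#' @param ld an \code{ld_score_table}
#' @param path file path
#' @export
write_ld_scores <- function(ld, path) {
  con <- file(path, "w")
  writeLines(sprintf("# M=%s n_ref=%s", attr(ld, "M"), attr(ld, "n_ref")), con)
  close(con)
  data.table::fwrite(ld, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_ld_scores
#' @export
read_ld_scores <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- suppressWarnings(as.integer(sub("^# M=(\\S+) n_ref=(\\S+)$", "\\1", hdr)))
  nref <- suppressWarnings(as.integer(sub("^# M=(\\S+) n_ref=(\\S+)$", "\\2", hdr)))
  df <- data.table::fread(path, skip = 1, header = TRUE, data.table = FALSE)
  structure(df, M = meta, n_ref = nref,
            class = c("ld_score_table", "data.frame"))
}

# ---- core weighted regression with leave-one-block-out ------------------
# y ~ a + b*x, weights w (fixed across blocks). Returns full-data (a, b)
# and the G x 2 matrix of delete-one-block estimates, computed from block
# sums so the jackknife is O(G) after one pass over the data.
wls_jackknife <- function(y, x, w, blocks) {
  g <- max(blocks)
  sw   <- rowsum(w, blocks)[, 1]
  swx  <- rowsum(w * x, blocks)[, 1]
  swxx <- rowsum(w * x * x, blocks)[, 1]
  swy  <- rowsum(w * y, blocks)[, 1]
  swxy <- rowsum(w * x * y, blocks)[, 1]
  tots <- c(sum(sw), sum(swx), sum(swxx), sum(swy), sum(swxy))
  est <- function(s) {
    den <- s[3] * s[1] - s[2]^2
    b <- (s[5] * s[1] - s[2] * s[4]) / den
    a <- (s[4] - b * s[2]) / s[1]
    c(a, b)
  }
  full <- est(tots)
  del <- matrix(NA_real_, g, 2)
  for (i in seq_len(g))
    del[i, ] <- est(tots - c(sw[i], swx[i], swxx[i], swy[i], swxy[i]))
  list(intercept = full[1], slope = full[2],
       del_intercept = del[, 1], del_slope = del[, 2])
}

# LDSC heteroskedasticity weights for one pair (a, b); a == b gives the h2
# weights 1 / (l * (1 + N h2 l / M)^2). Provisional slopes come from an
# unweighted first pass.
ldsc_weights <- function(l, xa, xb, h2a, h2b) {
  va <- pmax(1 + xa * h2a, 0.05)
  vb <- pmax(1 + xb * h2b, 0.05)
  1 / (pmax(l, 1) * va * vb)
}

#' Estimate SNP heritability by LD-score regression
#'
#' Regresses z^2 on n * l / M with a free intercept; the slope is h2 and
#' the intercept (1 + N a) absorbs confounding. Standard errors come from a
#' leave-one-block-out jackknife over contiguous variant blocks.
#'
#' @param z aligned z-score vector
#' @param n per-variant (or constant) sample size
#' @param ld an \code{ld_score_table} aligned to z
#' @param n_blocks number of contiguous jackknife blocks (>= 2)
#' @param weights \code{"ldsc"} (default; two-pass heteroskedasticity
#'   weights fixed from the full data) or \code{"unit"}
#' @param intercept \code{"free"} (default) or \code{"fixed"} (at 1)
#' @return an \code{ldsc_estimate} list: kind, estimate, se_jackknife,
#'   intercept, intercept_se, n_blocks, plus delete-block slope values
#' @export
estimate_h2 <- function(z, n, ld, n_blocks = 200, weights = c("ldsc", "unit"),
                        intercept = c("free", "fixed")) {
  estimate_gcov(z, z, n, n, ld, n_blocks = n_blocks, weights = weights,
                intercept = intercept, kind = "h2")
}

#' Estimate genetic covariance between two traits by cross-trait LDSC
#'
#' Regresses z_a * z_b on sqrt(n_a n_b) * l / M; the slope is the genetic
#' covariance rho_g and the free intercept absorbs sample overlap
#' (rho * N_s / sqrt(N_a N_b)).
#'
#' @inheritParams estimate_h2
#' @param z_a,z_b aligned z-score vectors on the same variant index
#' @param n_a,n_b sample sizes
#' @param kind internal; "gcov" or "h2"
#' @export
estimate_gcov <- function(z_a, z_b, n_a, n_b, ld, n_blocks = 200,
                          weights = c("ldsc", "unit"),
                          intercept = c("free", "fixed"),
                          kind = if (identical(z_a, z_b)) "h2" else "gcov") {
  if (!identical(weights, "unit")) weights <- match.arg(weights)
  intercept <- match.arg(intercept)
  m <- length(z_a)
  stopifnot(length(z_b) == m, nrow(ld) == m)
  if (any(!is.finite(z_a)) || any(!is.finite(z_b))) stop("non-finite z")
  if (n_blocks > m) stop("fewer variants (", m, ") than blocks (", n_blocks, ")")
  n_a <- rep_len(n_a, m); n_b <- rep_len(n_b, m)
  l <- ld$ldscore
  bigM <- attr(ld, "M") %||% m
  xa <- n_a * l / bigM
  xb <- n_b * l / bigM
  x  <- sqrt(n_a * n_b) * l / bigM
  y  <- z_a * z_b
  blocks <- block_ids(m, n_blocks)

  if (identical(weights, "unit")) {
    w <- rep(1, m)
  } else {
    # two-pass: provisional unweighted slopes for the variance terms
    h2a <- wls_jackknife(z_a^2, xa, rep(1, m), blocks)$slope
    h2b <- wls_jackknife(z_b^2, xb, rep(1, m), blocks)$slope
    w <- ldsc_weights(l, xa, xb, max(h2a, 0), max(h2b, 0))
  }

  if (intercept == "fixed") {
    y0 <- if (kind == "h2") y - 1 else y
    sw <- rowsum(w * x * x, blocks)[, 1]
    sy <- rowsum(w * x * y0, blocks)[, 1]
    slope <- sum(sy) / sum(sw)
    del_slope <- (sum(sy) - sy) / (sum(sw) - sw)
    fit <- list(intercept = if (kind == "h2") 1 else 0, slope = slope,
                del_intercept = rep(if (kind == "h2") 1 else 0, n_blocks),
                del_slope = del_slope)
  } else {
    fit <- wls_jackknife(y, x, w, blocks)
  }

  structure(list(kind = kind,
                 estimate = fit$slope,
                 se_jackknife = jackknife_se(fit$del_slope),
                 intercept = fit$intercept,
                 intercept_se = jackknife_se(fit$del_intercept),
                 n_blocks = n_blocks,
                 delete_values = fit$del_slope),
            class = "ldsc_estimate")
}

#' @export
print.ldsc_estimate <- function(x, ...) {
  cat(sprintf("ldsc_estimate [%s]: %.6g (SE %.3g), intercept %.4g (SE %.3g), %d blocks\n",
              x$kind, x$estimate, x$se_jackknife, x$intercept, x$intercept_se,
              x$n_blocks))
  invisible(x)
}

#' Build the genetic covariance matrix S and its sampling covariance V
#'
#' Runs LD-score regression for every trait (diagonal h2) and trait pair
#' (off-diagonal genetic covariance) of a harmonized panel, re-estimating
#' every element of vech(S) in a single shared leave-one-block-out
#' jackknife so that V captures the cross-element dependence induced by
#' shared variants and sample overlap.
#'
#' vech order is frozen as lower-triangle column-major (see [vech()]).
#'
#' @param panel a \code{harmonized_panel} with K >= 2 traits
#' @param ld an \code{ld_score_table} aligned to the panel's variants
#' @param n_blocks contiguous jackknife blocks (default 200, reduced to at
#'   most the variant count, never below 2)
#' @param weights,intercept passed to the pairwise estimators
#' @return an \code{sv_matrices} list: traits, S (K x K), V
#'   (K(K+1)/2 square), n_blocks, smoothed flag
#' @export
build_S_V <- function(panel, ld, n_blocks = 200,
                      weights = c("ldsc", "unit"),
                      intercept = c("free", "fixed")) {
  stopifnot(inherits(panel, "harmonized_panel"))
  k <- length(panel$traits)
  if (k < 2) stop("need K >= 2 traits")
  m <- nrow(panel$z)
  n_blocks <- max(2L, min(n_blocks, m))
  idx <- vech_index(k)
  nv <- nrow(idx)
  s_vec <- numeric(nv)
  dels <- matrix(NA_real_, n_blocks, nv)
  ses <- numeric(nv)
  for (p in seq_len(nv)) {
    i <- idx[p, 1]; j <- idx[p, 2]
    est <- tryCatch(
      estimate_gcov(panel$z[, i], panel$z[, j], panel$n[, i], panel$n[, j],
                    ld, n_blocks = n_blocks, weights = weights,
                    intercept = intercept),
      error = function(e) stop("estimation failed for pair (",
                               panel$traits[i], ", ", panel$traits[j], "): ",
                               conditionMessage(e)))
    s_vec[p] <- est$estimate
    ses[p] <- est$se_jackknife
    dels[, p] <- est$delete_values
  }
  ctr <- sweep(dels, 2, colMeans(dels))
  v <- (n_blocks - 1) / n_blocks * crossprod(ctr)
  s <- unvech(s_vec, k)
  dimnames(s) <- list(panel$traits, panel$traits)
  vnames <- paste0(panel$traits[idx[, 1]], ":", panel$traits[idx[, 2]])
  dimnames(v) <- list(vnames, vnames)
  structure(list(traits = panel$traits, S = s, V = v,
                 n_blocks = n_blocks, smoothed = FALSE,
                 pair_se = setNames(ses, vnames)),
            class = "sv_matrices")
}

#' @export
print.sv_matrices <- function(x, ...) {
  cat("sv_matrices:", length(x$traits), "traits,", x$n_blocks,
      "jackknife blocks", if (x$smoothed) "(smoothed)", "\nS:\n")
  print(round(x$S, 4))
  invisible(x)
}

#' Standardize an S/V pair to the genetic correlation scale
#'
#' Rescales S to a correlation matrix r_ij = s_ij / sqrt(s_ii s_jj) and
#' transforms V with the delta-method Jacobian of that map. Diagonal
#' moments become exact 1s with zero sampling variance.
#'
#' @param sv an \code{sv_matrices}
#' @return an \code{sv_matrices} on the correlation scale
#'   (\code{standardized = TRUE})
#' @export
to_correlation <- function(sv) {
  stopifnot(inherits(sv, "sv_matrices"))
  s <- sv$S
  k <- nrow(s)
  d <- diag(s)
  if (any(d <= 0))
    stop("non-positive heritability on the diagonal for trait(s): ",
         paste(sv$traits[d <= 0], collapse = ", "),
         "; smooth S or drop the trait before standardizing")
  r <- s / sqrt(outer(d, d))
  diag(r) <- 1
  idx <- vech_index(k)
  nv <- nrow(idx)
  pos_of <- matrix(0L, k, k)
  for (p in seq_len(nv)) {
    pos_of[idx[p, 1], idx[p, 2]] <- p
    pos_of[idx[p, 2], idx[p, 1]] <- p
  }
  jac <- matrix(0, nv, nv)
  for (p in seq_len(nv)) {
    i <- idx[p, 1]; j <- idx[p, 2]
    if (i == j) next  # diagonal of R is constant 1
    jac[p, p] <- 1 / sqrt(d[i] * d[j])
    jac[p, pos_of[i, i]] <- -r[i, j] / (2 * d[i])
    jac[p, pos_of[j, j]] <- -r[i, j] / (2 * d[j])
  }
  v <- jac %*% sv$V %*% t(jac)
  dimnames(v) <- dimnames(sv$V)
  out <- sv
  out$S <- r
  out$V <- v
  out$standardized <- TRUE
  out
}

#' Smooth the S and V of an sv_matrices object to positive semi-definite
#'
#' @param sv an \code{sv_matrices}
#' @param floor_frac eigenvalue floor fraction, see [smooth_to_psd()]
#' @export
smooth_sv <- function(sv, floor_frac = 1e-8) {
  s2 <- smooth_to_psd(sv$S, floor_frac)
  v2 <- smooth_to_psd(sv$V, floor_frac)
  changed <- max(attr(s2, "max_change"), attr(v2, "max_change"))
  sv$S <- s2; sv$V <- v2
  attr(sv$S, "max_change") <- NULL; attr(sv$V, "max_change") <- NULL
  sv$smoothed <- TRUE
  sv$smoothing_max_change <- changed
  sv
}

#' Write / read S and V as delimited matrices with a JSON sidecar
#'
#' S and V go to \code{<prefix>_S.tsv} and \code{<prefix>_V.tsv}; the
#' sidecar \code{<prefix>_meta.json} records trait order, the vech
#' convention, block count and smoothing state.
#'
#' @param sv an \code{sv_matrices}
#' @param prefix output path prefix
#' @export
write_sv <- function(sv, prefix) {
  s_path <- paste0(prefix, "_S.tsv"); v_path <- paste0(prefix, "_V.tsv")
  utils::write.table(sv$S, s_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  utils::write.table(sv$V, v_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  write_json_file(list(traits = as.list(sv$traits),
                       vech_order = "lower-triangle column-major",
                       n_blocks = sv$n_blocks,
                       smoothed = isTRUE(sv$smoothed),
                       standardized = isTRUE(sv$standardized)),
                  paste0(prefix, "_meta.json"))
  invisible(prefix)
}

#' @rdname write_sv
#' @export
read_sv <- function(prefix) {
  s <- as.matrix(utils::read.table(paste0(prefix, "_S.tsv"), header = TRUE,
                                   sep = "\t", check.names = FALSE))
  v <- as.matrix(utils::read.table(paste0(prefix, "_V.tsv"), header = TRUE,
                                   sep = "\t", check.names = FALSE))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  traits <- meta$traits
  dimnames(s) <- list(traits, traits)
  structure(list(traits = traits, S = s, V = v,
                 n_blocks = meta$n_blocks %||% NA_integer_,
                 smoothed = isTRUE(meta$smoothed),
                 standardized = isTRUE(meta$standardized)),
            class = "sv_matrices")
}
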
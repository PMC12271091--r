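# Diagonally weighted least squares estimation on an (S, V) pair.
#
# The fit function is F(theta) = sum_i (s_i - sigma_i(theta))^2 / V_ii over
# the half-vectorized unique moments (vech order frozen in utils.R).
# Standard errors are sandwich estimates using the FULL V:
#   (D' W D)^-1 D' W V W D (D' W D)^-1,  W = diag(V)^-1, D = d sigma / d theta.
# The model chi-square is the weighted residual statistic with a V-based
# mean correction (Satorra-Bentler style) so that its expectation under the
# model equals the degrees of freedom; `correction = "none"` gives the raw
# weighted sum of squared residuals.

jac_sigma <- function(spec, theta, eps = 1e-6) {
  base <- vech(implied_cov(spec, theta))
  q <- length(theta)
  jac <- matrix(0, length(base), q)
  for (p in seq_len(q)) {
    h <- eps * max(1, abs(theta[p]))
    tp <- theta; tp[p] <- tp[p] + h
    tm <- theta; tm[p] <- tm[p] - h
    jac[, p] <- (vech(implied_cov(spec, tp)) - vech(implied_cov(spec, tm))) / (2 * h)
  }
  jac
}

# scale-aware heuristic start values
start_values <- function(spec, s) {
  pt <- spec$partable
  obs <- spec$observed
  free_idx <- which(pt$free)
  th <- numeric(length(free_idx))
  typical_var <- mean(diag(s))
  for (k in seq_along(free_idx)) {
    r <- free_idx[k]
    op <- pt$op[r]; lhs <- pt$lhs[r]; rhs <- pt$rhs[r]
    if (op == "=~") {
      # loading start: sqrt of mean |cov| among this factor's indicators
      ind <- pt$rhs[pt$op == "=~" & pt$lhs == lhs]
      ind <- intersect(ind, obs)
      if (length(ind) >= 2) {
        sub <- s[ind, ind, drop = FALSE]
        off <- abs(sub[lower.tri(sub)])
        th[k] <- sqrt(max(mean(off), 1e-4 * typical_var))
      } else th[k] <- sqrt(typical_var) / 2
    } else if (op == "~") {
      th[k] <- 0
    } else if (lhs == rhs) {
      th[k] <- if (lhs %in% obs) 0.5 * s[lhs, lhs] else typical_var
    } else {
      th[k] <- if (lhs %in% obs && rhs %in% obs) 0.5 * s[lhs, rhs] else 0
    }
  }
  th
}

#' Fit a structural model to (S, V) by diagonally weighted least squares
#'
#' Minimizes the DWLS fit function by quasi-Newton iteration with an
#' analytic chain-rule gradient (finite-difference moment Jacobian),
#' restarting from jittered start values on non-convergence. Parameter
#' standard errors are full-V sandwich estimates; the model chi-square uses
#' a trace-based mean correction so its null reference is chi-square(df).
#'
#' @param sv an \code{sv_matrices} (covariance scale; V diagonal must be
#'   strictly positive — smooth first if needed)
#' @param spec a \code{model_spec} whose observed variables all appear in
#'   \code{sv$traits}
#' @param correction \code{"mean"} (default) or \code{"none"} for the raw
#'   weighted residual statistic
#' @param n_starts jittered restarts tried on non-convergence
#' @param seed RNG seed for the restart jitter
#' @return a \code{fit_result}: estimates, se, pvalues (per free parameter,
#'   partable order), vcov (sandwich), chisq, df, chisq_p, converged,
#'   n_iterations, objective, plus the inputs needed by [fit_indices()]
#' @export
fit_dwls <- function(sv, spec, correction = c("mean", "none"),
                     n_starts = 10, seed = 1L) {
  correction <- match.arg(correction)
  stopifnot(inherits(sv, "sv_matrices"), inherits(spec, "model_spec"))
  missing_tr <- setdiff(spec$observed, sv$traits)
  if (length(missing_tr) > 0)
    stop("observed variable(s) absent from sv: ",
         paste(missing_tr, collapse = ", "))
  s <- sv$S[spec$observed, spec$observed, drop = FALSE]

  k <- nrow(s)
  idx_full <- vech_index(length(sv$traits))
  # map this model's moments into sv's vech order to pick out V rows/cols
  ord <- match(spec$observed, sv$traits)
  idx_mod <- vech_index(k)
  pos_full <- matrix(0L, length(sv$traits), length(sv$traits))
  for (p in seq_len(nrow(idx_full))) {
    pos_full[idx_full[p, 1], idx_full[p, 2]] <- p
    pos_full[idx_full[p, 2], idx_full[p, 1]] <- p
  }
  sel <- vapply(seq_len(nrow(idx_mod)), function(p)
    pos_full[ord[idx_mod[p, 1]], ord[idx_mod[p, 2]]], 1L)
  v <- sv$V[sel, sel, drop = FALSE]

  s_vec <- vech(s)
  d <- diag(v)
  if (any(d <= 0))
    stop("V diagonal must be strictly positive; smooth_sv() first")
  w <- 1 / d

  pt <- spec$partable
  q <- sum(pt$free)
  nv <- length(s_vec)
  if (q > nv) stop("model has more free parameters than unique moments")

  skel <- ram_skeleton(spec)
  objective <- function(th) {
    sig <- tryCatch(vech(implied_parts(spec, th, skel)$sigma),
                    error = function(e) NULL)
    if (is.null(sig) || any(!is.finite(sig))) return(1e12)
    sum(w * (s_vec - sig)^2)
  }
  gradient <- function(th) {
    parts <- tryCatch(implied_parts(spec, th, skel), error = function(e) NULL)
    if (is.null(parts)) return(rep(0, length(th)))
    sig <- vech(parts$sigma)
    jac <- jac_sigma_ram(spec, th, skel, parts)
    -2 * as.numeric(crossprod(jac, w * (s_vec - sig)))
  }

  if (q == 0) {
    # fully fixed model: nothing to optimize
    theta <- numeric(0)
    parts <- implied_parts(spec, theta, ram_skeleton(spec))
    sig <- vech(parts$sigma)
    resid <- s_vec - sig
    t_naive <- sum(w * resid^2)
    chisq <- if (correction == "mean")
      t_naive / (sum(w * diag(v)) / nv) else t_naive   # U = W when q = 0
    return(structure(list(estimates = setNames(numeric(0), character(0)),
                          se = numeric(0), pvalues = numeric(0),
                          vcov = matrix(0, 0, 0), chisq = chisq, df = nv,
                          chisq_p = stats::pchisq(chisq, nv, lower.tail = FALSE),
                          converged = TRUE, n_iterations = 0L,
                          objective = t_naive, residuals = resid,
                          implied = unvech(sig, k),
                          s_vec = s_vec, v = v, w = w,
                          jac = matrix(0, nv, 0),
                          spec = spec, correction = correction),
                     class = "fit_result"))
  }

  th0 <- start_values(spec, s)
  best <- NULL
  set.seed(seed)
  starts <- c(list(th0), lapply(seq_len(n_starts), function(i)
    th0 * (1 + 0.3 * rnorm(length(th0))) + 0.1 * rnorm(length(th0)) * mean(abs(th0) + 1e-3)))
  n_iter_total <- 0
  for (st in starts) {
    res <- tryCatch(nlminb(st, objective, gradient,
                           control = list(iter.max = 500, eval.max = 2000)),
                    error = function(e) NULL)
    if (is.null(res)) next
    n_iter_total <- n_iter_total + res$iterations
    cand <- list(par = res$par, obj = res$objective,
                 conv = res$convergence == 0)
    if (is.null(best) || cand$obj < best$obj - 1e-12) best <- cand
    if (best$conv && best$obj < 1e8) break
  }
  if (is.null(best)) stop("all optimization attempts failed")
  # polish and verify stationarity with a second optimizer; nlminb's
  # convergence code is pessimistic on flat objectives
  pol <- tryCatch(optim(best$par, objective, gradient, method = "BFGS",
                        control = list(maxit = 200)),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$obj) {
    improved <- best$obj - pol$value
    best$par <- pol$par; best$obj <- pol$value
    if (improved < 1e-8 * (1 + abs(best$obj))) best$conv <- TRUE
  } else if (!is.null(pol)) {
    best$conv <- TRUE  # no further improvement possible: stationary
  }
  theta <- best$par
  converged <- isTRUE(best$conv)

  parts <- implied_parts(spec, theta, skel)
  sig <- vech(parts$sigma)
  resid <- s_vec - sig
  jac <- jac_sigma_ram(spec, theta, skel, parts)

  # sandwich covariance
  dwd <- crossprod(jac, w * jac)
  dwd_inv <- tryCatch(solve(dwd), error = function(e) {
    warning("bread matrix singular; using pseudo-inverse")
    ev <- eigen(dwd, symmetric = TRUE)
    keep <- ev$values > 1e-12 * max(ev$values)
    ev$vectors[, keep, drop = FALSE] %*%
      ((1 / ev$values[keep]) * t(ev$vectors[, keep, drop = FALSE]))
  })
  meat <- crossprod(w * jac, v %*% (w * jac))
  vtheta <- dwd_inv %*% meat %*% dwd_inv
  se <- sqrt(pmax(diag(vtheta), 0))

  df <- nv - q
  t_naive <- sum(w * resid^2)
  if (df > 0) {
    if (correction == "mean") {
      wj <- w * jac
      u <- diag(w) - wj %*% dwd_inv %*% t(wj)
      cfac <- sum(u * t(v)) / df    # tr(U V) / df
      chisq <- t_naive / cfac
    } else chisq <- t_naive
    chisq_p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  } else {
    chisq <- 0
    chisq_p <- NA_real_
  }

  free_labels <- pt$label[pt$free]
  est <- setNames(theta, free_labels)
  se <- setNames(se, free_labels)
  pvalues <- 2 * pnorm(-abs(est / ifelse(se > 0, se, NA)))

  res_var <- pt$op == "~~" & pt$lhs == pt$rhs
  neg <- res_var[pt$free] & theta < -1e-8 * max(abs(s_vec))
  if (any(neg))
    warning("Heywood case: negative residual variance for ",
            paste(free_labels[neg], collapse = ", "))

  structure(list(estimates = est, se = se, pvalues = pvalues,
                 vcov = vtheta, chisq = chisq, df = df, chisq_p = chisq_p,
                 converged = converged, n_iterations = n_iter_total,
                 objective = best$obj, residuals = resid,
                 implied = unvech(sig, k),
                 s_vec = s_vec, v = v, w = w, jac = jac,
                 spec = spec, correction = correction),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: chisq(%d) = %.3f (p = %.3g), converged = %s\n",
              x$df, x$chisq, x$chisq_p, x$converged))
  tab <- data.frame(estimate = x$estimates, se = x$se, p = x$pvalues)
  print(round(tab, 4))
  invisible(x)
}

#' Saturated model specification (all variances and covariances free)
#' @param observed character vector of observed variable names
#' @export
saturated_spec <- function(observed) {
  pairs <- utils::combn(observed, 2)
  txt <- paste(c(vapply(observed, function(v) paste(v, "~~", v), ""),
                 vapply(seq_len(ncol(pairs)), function(i)
                   paste(pairs[1, i], "~~", pairs[2, i]), "")),
               collapse = "\n")
  parse_model(txt)
}

# independence baseline: observed variances free, all covariances fixed 0
independence_spec <- function(observed) {
  txt <- paste(c(
    vapply(observed, function(v) paste(v, "~~", v), ""),
    {
      pairs <- utils::combn(observed, 2)
      vapply(seq_len(ncol(pairs)), function(i)
        paste0(pairs[1, i], " ~~ 0*", pairs[2, i]), "")
    }), collapse = "\n")
  parse_model(txt)
}

#' Fit indices for a DWLS solution
#'
#' CFI against the independence model (only variances free), SRMR on the
#' correlation-standardized scale over all unique moments (diagonal
#' residuals included), and AIC = chisq + 2q.
#'
#' @param result a converged \code{fit_result}
#' @param sv the \code{sv_matrices} the model was fitted to
#' @param spec the fitted \code{model_spec}
#' @return a \code{fit_indices} list: cfi, srmr, aic, chisq_independence,
#'   df_independence
#' @export
fit_indices <- function(result, sv, spec = result$spec) {
  stopifnot(inherits(result, "fit_result"))
  if (!result$converged) stop("fit did not converge; indices not computed")
  base <- fit_dwls(sv, independence_spec(spec$observed),
                   correction = result$correction)
  if (!base$converged) stop("independence baseline fit failed to converge")
  num <- max(result$chisq - result$df, 0)
  den <- max(base$chisq - base$df, result$chisq - result$df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den

  s <- sv$S[spec$observed, spec$observed, drop = FALSE]
  sig <- result$implied
  ds <- sqrt(diag(s))
  r_obs <- s / outer(ds, ds)
  r_imp <- sig / outer(ds, ds)   # standardized by OBSERVED sds (SRMR convention)
  resid <- vech(r_obs - r_imp)
  srmr <- sqrt(mean(resid^2))

  q <- sum(spec$partable$free)
  structure(list(cfi = cfi, srmr = srmr, aic = result$chisq + 2 * q,
                 chisq_independence = base$chisq,
                 df_independence = base$df),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("CFI = %.3f, SRMR = %.4f, AIC = %.2f\n", x$cfi, x$srmr, x$aic))
  invisible(x)
}

# standardized parameter values at theta (all variables unit variance)
standardized_values <- function(spec, theta, skel = ram_skeleton(spec)) {
  ram <- fill_ram(spec, theta, skel)
  inv <- solve(diag(skel$n) - ram$A)
  sig_all <- inv %*% ram$S %*% t(inv)
  sd_all <- sqrt(pmax(diag(sig_all), 0))
  if (any(sd_all == 0))
    stop("zero model-implied variance for: ",
         paste(skel$vars[sd_all == 0], collapse = ", "))
  pt <- spec$partable
  free_idx <- which(pt$free)
  out <- numeric(length(free_idx))
  for (k in seq_along(free_idx)) {
    r <- free_idx[k]
    l <- skel$loc[[r]]
    if (l$mat == "A") {
      out[k] <- (ram$A[l$i, l$j]) * sd_all[l$j] / sd_all[l$i]
    } else if (l$i == l$j) {
      out[k] <- ram$S[l$i, l$i] / sig_all[l$i, l$i]  # residual proportion
    } else {
      out[k] <- ram$S[l$i, l$j] / (sd_all[l$i] * sd_all[l$j])
    }
  }
  setNames(out, pt$label[free_idx])
}

#' Standardize a fitted solution to the correlation metric
#'
#' Rescales every estimate so that all observed and latent variables have
#' unit model-implied variance (loadings and regressions become
#' standardized coefficients, covariances become correlations, residual
#' variances become residual proportions). Standard errors are transformed
#' by the delta method using the sandwich covariance of theta.
#'
#' @param result a converged \code{fit_result}
#' @param spec the fitted \code{model_spec}
#' @return a \code{fit_result} with standardized estimates/se/pvalues;
#'   chi-square and df are unchanged
#' @export
standardize_solution <- function(result, spec = result$spec) {
  stopifnot(inherits(result, "fit_result"))
  theta <- unname(result$estimates)
  skel <- ram_skeleton(spec)
  std <- standardized_values(spec, theta, skel)
  q <- length(theta)
  jac <- matrix(0, q, q)
  for (p in seq_len(q)) {
    h <- 1e-6 * max(1, abs(theta[p]))
    tp <- theta; tp[p] <- tp[p] + h
    tm <- theta; tm[p] <- tm[p] - h
    jac[, p] <- (standardized_values(spec, tp, skel) -
                   standardized_values(spec, tm, skel)) / (2 * h)
  }
  vstd <- jac %*% result$vcov %*% t(jac)
  se <- setNames(sqrt(pmax(diag(vstd), 0)), names(std))
  out <- result
  out$estimates <- std
  out$se <- se
  out$pvalues <- 2 * pnorm(-abs(std / ifelse(se > 0, se, NA)))
  out$vcov <- vstd
  out$standardized <- TRUE
  out
}
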
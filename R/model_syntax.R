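# Declarative model syntax, lavaan-flavoured:
#   F =~ a + b + c        factor loadings
#   x ~~ y                (co)variance; x ~~ x is a variance
#   y ~ x1 + x2           regression of y on predictors
#   0*C, 0.5*x            fixed-constant prefix on a right-hand term
# Lines are separated by newlines or ';'; '#' starts a comment.
#
# A parsed model is a "model_spec": a parameter table (lhs, op, rhs, free,
# value, label) plus bookkeeping (latents, observed, identification rule).
# Defaults applied after parsing: every observed variable gets a free
# residual variance unless one was declared; each latent is identified
# either by a unit variance (default; all loadings free) or by fixing its
# first loading to 1 (marker_loading; variance free).

parse_rhs_term <- function(term, lineno) {
  term <- trimws(term)
  if (grepl("\\*", term)) {
    parts <- strsplit(term, "\\*")[[1]]
    if (length(parts) != 2)
      stop("parse error at line ", lineno, ": bad term '", term, "'")
    val <- suppressWarnings(as.numeric(trimws(parts[1])))
    if (is.na(val))
      stop("parse error at line ", lineno, ": non-numeric fixed value in '",
           term, "'")
    list(var = trimws(parts[2]), fixed = TRUE, value = val)
  } else {
    list(var = term, fixed = FALSE, value = NA_real_)
  }
}

#' Parse model syntax into a model specification
#'
#' @param text model syntax string (see package vignette for the grammar)
#' @param identification per-latent identification rule:
#'   \code{"unit_variance"} (latent variances fixed at 1, all loadings free)
#'   or \code{"marker_loading"} (first loading fixed at 1, variance free)
#' @param observed_order optional character vector fixing the order of
#'   observed variables (defaults to order of first appearance)
#' @return a \code{model_spec} with elements \code{partable} (data.frame),
#'   \code{latents}, \code{observed}, \code{identification}
#' @export
parse_model <- function(text, identification = c("unit_variance", "marker_loading"),
                        observed_order = NULL) {
  identification <- match.arg(identification)
  stopifnot(is.character(text), nzchar(paste(text, collapse = "")))
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "[\n;]"))
  lines <- sub("#.*$", "", lines)
  rows <- list()
  latents <- character()
  seen <- character()
  add_row <- function(lhs, op, rhs, free, value) {
    rows[[length(rows) + 1]] <<- data.frame(lhs = lhs, op = op, rhs = rhs,
                                            free = free, value = value,
                                            stringsAsFactors = FALSE)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    op <- if (grepl("=~", ln, fixed = TRUE)) "=~"
          else if (grepl("~~", ln, fixed = TRUE)) "~~"
          else if (grepl("~", ln, fixed = TRUE)) "~"
          else stop("parse error at line ", i, ": no operator in '", ln, "'")
    parts <- strsplit(ln, op, fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("parse error at line ", i, ": expected 'lhs ", op, " rhs'")
    lhs <- trimws(parts[1])
    if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", lhs))
      stop("parse error at line ", i, ": bad variable name '", lhs, "'")
    terms <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
    if (op == "=~") latents <- union(latents, lhs)
    seen <- union(seen, lhs)
    for (tm in terms) {
      t <- parse_rhs_term(tm, i)
      if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", t$var))
        stop("parse error at line ", i, ": bad variable name '", t$var, "'")
      seen <- union(seen, t$var)
      add_row(lhs, op, t$var, !t$fixed, t$value)
    }
  }
  pt <- do.call(rbind, rows)
  if (is.null(pt)) stop("empty model")

  observed <- setdiff(seen, latents)
  if (!is.null(observed_order)) {
    unknown <- setdiff(observed, observed_order)
    if (length(unknown) > 0)
      stop("observed variable(s) not in observed_order: ",
           paste(unknown, collapse = ", "))
    observed <- intersect(observed_order, observed)
  }

  # identification per latent
  for (f in latents) {
    load_idx <- which(pt$op == "=~" & pt$lhs == f)
    has_fixed_load <- any(!pt$free[load_idx])
    var_idx <- which(pt$op == "~~" & pt$lhs == f & pt$rhs == f)
    has_var <- length(var_idx) > 0
    if (length(load_idx) < 2 && !has_fixed_load && !has_var)
      stop("under-identified latent '", f,
           "': fewer than 2 indicators and no fixed constraint")
    if (identification == "unit_variance") {
      if (!has_var)
        pt <- rbind(pt, data.frame(lhs = f, op = "~~", rhs = f, free = FALSE,
                                   value = 1, stringsAsFactors = FALSE))
    } else {
      if (!has_fixed_load && length(load_idx) > 0) {
        pt$free[load_idx[1]] <- FALSE
        pt$value[load_idx[1]] <- 1
      }
      if (!has_var)
        pt <- rbind(pt, data.frame(lhs = f, op = "~~", rhs = f, free = TRUE,
                                   value = NA_real_, stringsAsFactors = FALSE))
    }
  }

  # free residual variances for observed variables lacking one
  for (v in observed) {
    if (!any(pt$op == "~~" & pt$lhs == v & pt$rhs == v))
      pt <- rbind(pt, data.frame(lhs = v, op = "~~", rhs = v, free = TRUE,
                                 value = NA_real_, stringsAsFactors = FALSE))
  }

  # canonicalize covariance ordering (alphabetical pair key) and drop dups
  swap <- pt$op == "~~" & pt$lhs > pt$rhs
  tmp <- pt$lhs[swap]; pt$lhs[swap] <- pt$rhs[swap]; pt$rhs[swap] <- tmp
  key <- paste(pt$lhs, pt$op, pt$rhs)
  if (anyDuplicated(key))
    stop("duplicated parameter line(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  pt$label <- paste0(pt$lhs, pt$op, pt$rhs)
  pt$id <- seq_len(nrow(pt))
  rownames(pt) <- NULL
  structure(list(partable = pt, latents = latents, observed = observed,
                 identification = identification),
            class = "model_spec")
}

#' Serialize a model_spec back to model syntax
#' @param spec a \code{model_spec}
#' @return character scalar of model syntax
#' @export
serialize_model <- function(spec) {
  pt <- spec$partable
  fmt <- function(row) {
    rhs <- if (row$free) row$rhs else paste0(row$value, "*", row$rhs)
    paste(row$lhs, row$op, rhs)
  }
  paste(vapply(seq_len(nrow(pt)), function(i) fmt(pt[i, ]), ""),
        collapse = "\n")
}

#' Number of free parameters of a model
#' @param spec a \code{model_spec}
#' @export
n_free_params <- function(spec) sum(spec$partable$free)

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", length(x$observed), "observed,",
      length(x$latents), "latents,", n_free_params(x), "free parameters (",
      x$identification, ")\n", sep = " ")
  print(x$partable[, c("lhs", "op", "rhs", "free", "value")])
  invisible(x)
}

# ---- RAM assembly ------------------------------------------------------
# Variables are ordered observed-then-latent. A holds directed paths
# (A[child, parent]: loadings obs <- latent and regressions y <- x);
# Smat holds variances and covariances of the residual/exogenous parts.
# Sigma_all = (I - A)^-1 Smat (I - A)^-T ; Sigma_obs is its observed block.

ram_skeleton <- function(spec) {
  vars <- c(spec$observed, spec$latents)
  nv <- length(vars)
  pt <- spec$partable
  loc <- vector("list", nrow(pt))
  for (r in seq_len(nrow(pt))) {
    li <- match(pt$lhs[r], vars); ri <- match(pt$rhs[r], vars)
    if (is.na(li) || is.na(ri))
      stop("unknown variable in parameter '", pt$label[r], "'")
    loc[[r]] <- switch(pt$op[r],
      "=~" = list(mat = "A", i = ri, j = li),   # indicator <- latent
      "~"  = list(mat = "A", i = li, j = ri),   # outcome <- predictor
      "~~" = list(mat = "S", i = li, j = ri))
  }
  list(vars = vars, n = nv, loc = loc, obs_idx = seq_along(spec$observed))
}

fill_ram <- function(spec, theta, skel = ram_skeleton(spec)) {
  pt <- spec$partable
  a <- matrix(0, skel$n, skel$n)
  s <- matrix(0, skel$n, skel$n)
  free_idx <- which(pt$free)
  stopifnot(length(theta) == length(free_idx))
  vals <- pt$value
  vals[free_idx] <- theta
  for (r in seq_len(nrow(pt))) {
    l <- skel$loc[[r]]
    if (l$mat == "A") a[l$i, l$j] <- vals[r]
    else { s[l$i, l$j] <- vals[r]; s[l$j, l$i] <- vals[r] }
  }
  list(A = a, S = s)
}

# implied covariance plus the pieces the analytic Jacobian needs
implied_parts <- function(spec, theta, skel) {
  ram <- fill_ram(spec, theta, skel)
  ia <- diag(skel$n) - ram$A
  inv <- tryCatch(solve(ia),
                  error = function(e) stop("(I - A) is singular: cyclic regression"))
  p <- inv %*% ram$S %*% t(inv)
  sig <- p[skel$obs_idx, skel$obs_idx, drop = FALSE]
  list(sigma = (sig + t(sig)) / 2, inv = inv, P = p)
}

# analytic d vech(Sigma_obs) / d theta via RAM algebra:
#   A-parameter (i <- j): dSigma = G + G',  G = outer(inv[obs, i], P[j, obs])
#   S-parameter (i, j):   dSigma = outer(inv[obs,i], inv[obs,j]) (+ transpose
#                         when i != j)
jac_sigma_ram <- function(spec, theta, skel, parts = implied_parts(spec, theta, skel)) {
  pt <- spec$partable
  free_rows <- which(pt$free)
  obs <- skel$obs_idx
  lower <- lower.tri(diag(length(obs)), diag = TRUE)
  jac <- matrix(0, sum(lower), length(free_rows))
  invo <- parts$inv[obs, , drop = FALSE]
  for (kk in seq_along(free_rows)) {
    l <- skel$loc[[free_rows[kk]]]
    if (l$mat == "A") {
      g <- outer(invo[, l$i], parts$P[l$j, obs])
      d <- g + t(g)
    } else if (l$i == l$j) {
      d <- outer(invo[, l$i], invo[, l$i])
    } else {
      g <- outer(invo[, l$i], invo[, l$j])
      d <- g + t(g)
    }
    jac[, kk] <- d[lower]
  }
  jac
}

#' Model-implied covariance matrix of the observed variables
#'
#' Assembles the implied covariance from the RAM representation
#' Sigma = F (I - A)^-1 S (I - A)^-T F'. Free parameters are supplied in
#' partable order.
#'
#' @param spec a \code{model_spec}
#' @param theta numeric vector of free-parameter values (partable order)
#' @return K x K symmetric matrix over \code{spec$observed}
#' @export
implied_cov <- function(spec, theta) {
  skel <- ram_skeleton(spec)
  ram <- fill_ram(spec, theta, skel)
  ia <- diag(skel$n) - ram$A
  inv <- tryCatch(solve(ia),
                  error = function(e) stop("(I - A) is singular: cyclic regression"))
  sig <- inv %*% ram$S %*% t(inv)
  out <- sig[skel$obs_idx, skel$obs_idx, drop = FALSE]
  dimnames(out) <- list(spec$observed, spec$observed)
  (out + t(out)) / 2
}
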
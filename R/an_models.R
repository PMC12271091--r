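# Pre-built model specifications for the anorexia-nervosa / impulsivity /
# substance-use-disorder analysis: a correlated-factor model and a multiple
# regression of AN on all impulsivity and SUD predictors.
#
# Canonical trait labels:
#   NU, PU          UPPS-P negative / positive urgency
#   PREMED          UPPS-P (lack of) premeditation
#   ATT, MOT, NONPLAN  BIS attentional / motor / non-planning
#   PERSEV          lack of perseverance      SS   sensation seeking
#   DD              delay discounting (higher = steeper discounting)
#   PAU, CUD, OUD, TUD  problematic alcohol / cannabis / opioid / tobacco
#   AN              anorexia nervosa

#' Configuration of the AN / impulsivity / SUD model family
#'
#' The common-impulsivity factor loads on six UPPS-P/BIS subscales by
#' default (set \code{common_impulsivity_indicators} to the four-subscale
#' variant to drop BIS attentional and motor). The urgency-specific factor
#' loads on negative and positive urgency only and is orthogonal to common
#' impulsivity. The four SUDs form a single factor; delay discounting,
#' sensation seeking and lack of perseverance enter as single indicators.
#'
#' @param common_impulsivity_indicators character vector
#' @param urgency_indicators subset of the common indicators
#' @param sud_indicators character vector
#' @param singles single-indicator traits modeled alongside the factors
#' @param outcome outcome trait (regression model)
#' @return a \code{an_model_config} list
#' @export
an_model_config <- function(
    common_impulsivity_indicators = c("NU", "PU", "PREMED", "ATT", "MOT", "NONPLAN"),
    urgency_indicators = c("NU", "PU"),
    sud_indicators = c("PAU", "CUD", "OUD", "TUD"),
    singles = c("DD", "SS", "PERSEV"),
    outcome = "AN") {
  if (!all(urgency_indicators %in% common_impulsivity_indicators))
    stop("urgency_indicators must be a subset of common_impulsivity_indicators")
  all_ind <- c(common_impulsivity_indicators, sud_indicators, singles)
  if (outcome %in% all_ind)
    stop("outcome '", outcome, "' must not appear among the indicators")
  structure(list(common_impulsivity_indicators = common_impulsivity_indicators,
                 urgency_indicators = urgency_indicators,
                 sud_indicators = sud_indicators,
                 singles = singles, outcome = outcome),
            class = "an_model_config")
}

model_entities <- function(config) {
  c("CI", "URG", "SUD", config$singles, config$outcome)
}

factor_block <- function(config) {
  c(paste("CI =~", paste(config$common_impulsivity_indicators, collapse = " + ")),
    paste("URG =~", paste(config$urgency_indicators, collapse = " + ")),
    paste("SUD =~", paste(config$sud_indicators, collapse = " + ")),
    "CI ~~ 0*URG")
}

check_config_traits <- function(config, available) {
  if (is.null(available)) return(invisible())
  need <- c(config$common_impulsivity_indicators, config$sud_indicators,
            config$singles, config$outcome)
  missing <- setdiff(need, available)
  if (length(missing) > 0)
    stop("indicator(s) absent from available traits: ",
         paste(missing, collapse = ", "))
}

#' Correlated-factor model of AN, impulsivity facets, and SUDs
#'
#' Two impulsivity factors (common impulsivity over the UPPS-P/BIS
#' subscales; an orthogonal urgency-specific factor over negative and
#' positive urgency), a single SUD factor over the four disorders, and
#' delay discounting, sensation seeking, lack of perseverance and AN as
#' observed variables. All factor-factor, factor-single and single-single
#' covariances are free except the fixed-zero covariance between the two
#' impulsivity factors.
#'
#' @param config a \code{an_model_config}
#' @param available optional character vector of available trait labels;
#'   indicators missing from it raise an error naming them
#' @return a \code{model_spec}
#' @export
correlated_factors_model <- function(config = an_model_config(),
                                     available = NULL) {
  check_config_traits(config, available)
  ent <- model_entities(config)
  pairs <- utils::combn(ent, 2)
  cov_lines <- vapply(seq_len(ncol(pairs)), function(i)
    paste(pairs[1, i], "~~", pairs[2, i]), "")
  cov_lines <- setdiff(cov_lines, c("CI ~~ URG", "URG ~~ CI"))
  txt <- paste(c(factor_block(config), cov_lines), collapse = "\n")
  parse_model(txt, identification = "unit_variance")
}

#' Multiple-regression model: AN regressed on all factors and singles
#'
#' Identical measurement structure to [correlated_factors_model()], but the
#' outcome's covariances are replaced by directed paths from common
#' impulsivity, urgency-specific impulsivity, the SUD factor, and each
#' single indicator; the outcome keeps a free residual variance.
#'
#' @inheritParams correlated_factors_model
#' @param drop_predictors predictors to omit (e.g. \code{"SUD"} for the
#'   unconditioned contrast)
#' @return a \code{model_spec}
#' @export
regression_model <- function(config = an_model_config(), available = NULL,
                             drop_predictors = character()) {
  check_config_traits(config, available)
  preds <- setdiff(c("CI", "URG", "SUD", config$singles), drop_predictors)
  # dropped predictors stay in the covariance structure; only the path goes
  ent <- setdiff(model_entities(config), config$outcome)
  pairs <- utils::combn(ent, 2)
  cov_lines <- vapply(seq_len(ncol(pairs)), function(i)
    paste(pairs[1, i], "~~", pairs[2, i]), "")
  cov_lines <- setdiff(cov_lines, c("CI ~~ URG", "URG ~~ CI"))
  reg_line <- paste(config$outcome, "~", paste(preds, collapse = " + "))
  txt <- paste(c(factor_block(config), cov_lines, reg_line), collapse = "\n")
  parse_model(txt, identification = "unit_variance")
}

#' Fit both models of the AN/impulsivity/SUD family and report
#'
#' Fits the correlated-factor and regression models to one (S, V) pair,
#' standardizes the solutions, computes fit indices, applies the fit
#' thresholds (CFI > 0.95 good / > 0.90 acceptable; SRMR < 0.08), and
#' asserts the expected sign convention (higher delay-discounting score =
#' steeper discounting, so the outcome-DD association is reported with its
#' sign).
#'
#' @param sv an \code{sv_matrices} on the covariance scale
#' @param config a \code{an_model_config}
#' @param rename optional named character vector mapping sv trait labels to
#'   canonical labels (names = labels in \code{sv$traits}, values =
#'   canonical)
#' @return a \code{replication_report} list with one entry per model:
#'   fit, standardized fit, indices, and a flat summary table
#' @export
replicate_models <- function(sv, config = an_model_config(), rename = NULL) {
  stopifnot(inherits(sv, "sv_matrices"))
  if (!is.null(rename)) {
    pos <- match(names(rename), sv$traits)
    if (anyNA(pos)) stop("rename refers to unknown traits: ",
                         paste(names(rename)[is.na(pos)], collapse = ", "))
    sv$traits[pos] <- unname(rename)
    dimnames(sv$S) <- list(sv$traits, sv$traits)
  }
  need <- c(config$common_impulsivity_indicators, config$sud_indicators,
            config$singles, config$outcome)
  missing <- setdiff(need, sv$traits)
  if (length(missing) > 0)
    stop("trait label(s) not found in sv: ", paste(missing, collapse = ", "))

  out <- list(config = config)
  for (model in c("correlated", "regression")) {
    spec <- if (model == "correlated") correlated_factors_model(config, sv$traits)
            else regression_model(config, sv$traits)
    fit <- fit_dwls(sv, spec)
    std <- standardize_solution(fit, spec)
    idx <- fit_indices(fit, sv, spec)
    verdict <- if (idx$cfi > 0.95 && idx$srmr < 0.08) "good"
               else if (idx$cfi >= 0.90 && idx$srmr < 0.08) "acceptable"
               else "poor"
    summary_tab <- data.frame(parameter = names(std$estimates),
                              estimate = unname(std$estimates),
                              se = unname(std$se),
                              p = unname(std$pvalues),
                              stringsAsFactors = FALSE)
    out[[model]] <- list(spec = spec, fit = fit, standardized = std,
                         indices = idx, verdict = verdict,
                         summary = summary_tab)
  }
  # sign-convention check on the standardized outcome-DD association
  an_dd <- paste0(min(config$outcome, "DD"), "~~", max(config$outcome, "DD"))
  cf <- out$correlated$standardized$estimates
  out$an_dd_rg <- unname(cf[an_dd])
  class(out) <- "replication_report"
  out
}

#' @export
print.replication_report <- function(x, ...) {
  for (model in c("correlated", "regression")) {
    m <- x[[model]]
    cat("==", model, "model: chisq(", m$fit$df, ") = ",
        sprintf("%.2f", m$fit$chisq),
        ", CFI = ", sprintf("%.3f", m$indices$cfi),
        ", SRMR = ", sprintf("%.4f", m$indices$srmr),
        ", AIC = ", sprintf("%.2f", m$indices$aic),
        " [", m$verdict, "]\n", sep = "")
  }
  cat("standardized outcome-DD genetic correlation:",
      sprintf("%.3f", x$an_dd_rg), "\n")
  invisible(x)
}

#' Serialize a replication report to JSON (plus a markdown table)
#'
#' @param report a \code{replication_report}
#' @param path output JSON path; \code{sub("json$", "md", path)} receives a
#'   markdown summary table
#' @export
write_report <- function(report, path) {
  to_list <- function(m) list(
    chisq = m$fit$chisq, df = m$fit$df, chisq_p = m$fit$chisq_p,
    cfi = m$indices$cfi, srmr = m$indices$srmr, aic = m$indices$aic,
    verdict = m$verdict, converged = m$fit$converged,
    estimates = as.list(m$standardized$estimates),
    se = as.list(m$standardized$se),
    p = as.list(m$standardized$pvalues))
  write_json_file(list(correlated = to_list(report$correlated),
                       regression = to_list(report$regression),
                       an_dd_rg = report$an_dd_rg), path)
  md <- c("| model | chisq | df | CFI | SRMR | AIC | verdict |",
          "|---|---|---|---|---|---|---|")
  for (model in c("correlated", "regression")) {
    m <- report[[model]]
    md <- c(md, sprintf("| %s | %.2f | %d | %.3f | %.4f | %.2f | %s |",
                        model, m$fit$chisq, m$fit$df, m$indices$cfi,
                        m$indices$srmr, m$indices$aic, m$verdict))
  }
  writeLines(md, sub("json$", "md", path))
  invisible(path)
}
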
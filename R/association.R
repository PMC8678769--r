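#' Odds ratio and Wald confidence interval from a log-odds estimate
#'
#' @param coef log-odds-ratio estimate.
#' @param se its standard error (>= 0).
#' @param level confidence level, default 0.95.
#' @return named numeric `c(or, ci_low, ci_high)`.
#' @export
odds_ratio_ci <- function(coef, se, level = 0.95) {
  stopifnot(se >= 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  coef <- unname(coef); se <- unname(se)
  c(or = exp(coef), ci_low = exp(coef - z * se), ci_high = exp(coef + z * se))
}

## logistic fit with convergence / separation flag; glm is the IRLS engine
fit_logistic <- function(formula, data, max_coef = 15) {
  fit <- suppressWarnings(stats::glm(formula, data = data, family = stats::binomial()))
  cf <- stats::coef(fit)
  conv <- isTRUE(fit$converged) && all(is.finite(cf)) && max(abs(cf[-1L]), 0) < max_coef
  list(fit = fit, converged = conv)
}

#' Univariate covariate screening for the adjusted outcome model
#'
#' Screens candidate covariates one at a time with a univariate logistic
#' regression of the outcome on the covariate, keeping those whose Wald p
#' value is below `threshold` (the conventional p < .1 entry rule for the
#' fully adjusted model). Column order is preserved; constant covariates are
#' excluded with a warning. For a categorical covariate the smallest level p
#' value is used.
#'
#' @param covariates data frame of candidate covariates.
#' @param outcome binary 0/1 vector.
#' @param threshold screening p-value threshold, default 0.1.
#' @return character vector of selected covariate names (possibly empty).
#' @export
screen_covariates <- function(covariates, outcome, threshold = 0.1) {
  stopifnot(is.data.frame(covariates))
  if (ncol(covariates) == 0L) return(character(0))
  keep <- character(0)
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning("covariate '", nm, "' is constant; excluded from screening")
      next
    }
    d <- data.frame(y = outcome, x = x)
    fl <- fit_logistic(y ~ x, d)
    if (!fl$converged) next
    ct <- summary(fl$fit)$coefficients
    p <- min(ct[-1L, "Pr(>|z|)"])
    if (is.finite(p) && p < threshold) keep <- c(keep, nm)
  }
  keep
}

#' Association between trajectory groups and a binary outcome
#'
#' Fits the three nested logistic models relating trajectory-group membership
#' to a binary stroke outcome: model 1 is unadjusted (group indicators only,
#' dummy-coded against the reference group); model 2 adds the demographic
#' covariates; model 3 adds all remaining covariates passing the univariate
#' screen (p < `screen_threshold`). One result row is produced per
#' non-reference group per model, with odds ratio, 95\% Wald CI and p value.
#'
#' @param groups group labels (integer or factor), one per patient.
#' @param outcome binary 0/1 vector, same length.
#' @param reference the reference (control) group label.
#' @param covariates optional data frame of per-patient covariates.
#' @param demographics names of `covariates` columns entering model 2
#'   (default `age` and `sex` where present).
#' @param models which of models 1-3 to fit.
#' @param screen_threshold univariate screening p threshold for model 3.
#' @param level CI level.
#' @return data frame with columns `model`, `group`, `or`, `ci_low`,
#'   `ci_high`, `p`, `converged`. The reference group has no rows.
#' @export
trajectory_association <- function(groups, outcome, reference,
                                   covariates = NULL,
                                   demographics = intersect(c("age", "sex"),
                                                            names(covariates)),
                                   models = 1:3, screen_threshold = 0.1,
                                   level = 0.95) {
  groups <- as.factor(groups)
  if (!as.character(reference) %in% levels(groups))
    stop("reference group '", reference, "' not present")
  if (length(unique(outcome[!is.na(outcome)])) < 2L)
    stop("outcome must contain both classes")
  groups <- stats::relevel(groups, ref = as.character(reference))
  empty <- levels(groups)[tabulate(groups, nlevels(groups)) == 0L]
  if (length(empty)) {
    warning("dropping empty group level(s): ", paste(empty, collapse = ", "))
    groups <- droplevels(groups)
  }
  base <- data.frame(.y = outcome, .g = groups)
  if (!is.null(covariates)) base <- cbind(base, covariates)

  others <- if (is.null(covariates)) character(0)
            else setdiff(names(covariates), demographics)
  screened <- if (3L %in% models && length(others))
    screen_covariates(covariates[others], outcome, screen_threshold)
  else character(0)

  rhs <- list(`1` = ".g",
              `2` = paste(c(".g", demographics), collapse = " + "),
              `3` = paste(c(".g", demographics, screened), collapse = " + "))
  out <- list()
  for (m in models) {
    f <- stats::as.formula(paste(".y ~", rhs[[as.character(m)]]))
    fl <- fit_logistic(f, base)
    ct <- summary(fl$fit)$coefficients
    gterms <- paste0(".g", setdiff(levels(groups), as.character(reference)))
    for (gt in gterms) {
      if (!gt %in% rownames(ct)) next
      oc <- odds_ratio_ci(ct[gt, "Estimate"], ct[gt, "Std. Error"], level)
      out[[length(out) + 1L]] <- data.frame(
        model = m, group = sub("^\\.g", "", gt),
        or = oc[["or"]], ci_low = oc[["ci_low"]], ci_high = oc[["ci_high"]],
        p = ct[gt, "Pr(>|z|)"], converged = fl$converged)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "screened") <- screened
  res
}

#' Odds ratio of a continuous BP parameter for a binary outcome
#'
#' Unadjusted logistic regression of the outcome on a single continuous
#' predictor, reported per unit (per mmHg) by default or per SD.
#'
#' @param x continuous predictor.
#' @param outcome binary 0/1 vector.
#' @param per `"unit"` or `"sd"` scaling of the reported OR.
#' @param level CI level.
#' @return data frame with `or`, `ci_low`, `ci_high`, `p`, `converged`.
#' @export
parameter_association <- function(x, outcome, per = c("unit", "sd"),
                                  level = 0.95) {
  per <- match.arg(per)
  if (per == "sd") x <- x / stats::sd(x, na.rm = TRUE)
  fl <- fit_logistic(y ~ x, data.frame(y = outcome, x = x))
  ct <- summary(fl$fit)$coefficients
  oc <- odds_ratio_ci(ct["x", "Estimate"], ct["x", "Std. Error"], level)
  data.frame(or = oc[["or"]], ci_low = oc[["ci_low"]], ci_high = oc[["ci_high"]],
             p = ct["x", "Pr(>|z|)"], converged = fl$converged)
}

#' ROC area under the curve with Hanley-McNeil inference
#'
#' Computes the AUC as the Mann-Whitney two-sample statistic
#' \eqn{U/(n_1 n_0)} with ties counted one half, its approximate 95\% CI by
#' the Hanley-McNeil normal method, and a two-sided p value against
#' AUC = 0.5.
#'
#' @param scores numeric predictor scores.
#' @param labels binary 0/1 outcome labels.
#' @param level CI level, default 0.95.
#' @return data frame with `auc`, `ci_low`, `ci_high` (clipped to [0, 1])
#'   and `p`.
#' @export
roc_auc <- function(scores, labels, level = 0.95) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: both classes required")
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
  data.frame(auc = auc, ci_low = max(0, auc - z * se),
             ci_high = min(1, auc + z * se), p = p)
}
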
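#' @export
print.gbtm <- function(x, digits = 4, ...) {
  cat(sprintf("Group-based trajectory model: %d group%s, censored-normal residuals\n",
              x$ngroups, if (x$ngroups > 1L) "s" else ""))
  cat(sprintf("  %d patients, %d observations; logLik %.2f, AIC %.1f, BIC %.1f\n",
              x$n_patients, x$n_obs, x$logLik, x$aic, x$bic))
  cat(sprintf("  residual SD: %s mmHg; %sconverged in %d EM iterations\n",
              paste(formatC(x$sigma, digits = digits, format = "g"), collapse = ", "),
              if (x$converged) "" else "NOT ", x$iterations))
  tab <- data.frame(group = seq_len(x$ngroups),
                    order = x$orders,
                    pi = round(x$pi, 3),
                    share = round(tabulate(x$assignments, x$ngroups) / x$n_patients, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gbtm <- function(object, ...) object$coefficients

#' @export
logLik.gbtm <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n_patients,
            class = "logLik")
}

#' Mixture log-likelihood of data under a fitted trajectory model
#'
#' Evaluates the observed-data log-likelihood
#' \eqn{\sum_i \log \sum_j \pi_j L_{ij}} for (possibly new) long-format data,
#' computed stably in the log domain.
#'
#' @param object a fitted `gbtm` model.
#' @param data long-format data frame; defaults to the training data.
#' @param formula formula `value ~ time | id`; defaults to the fitting formula.
#' @return scalar log-likelihood.
#' @export
gbtm_loglik <- function(object, data = NULL, formula = object$formula) {
  stopifnot(inherits(object, "gbtm"))
  if (is.null(data)) return(object$logLik)
  d <- parse_gbtm_formula(formula, data)
  B <- outer(d$t, 0:max(object$orders), `^`)
  L <- gbtm_group_loglik(d$y, d$id, d$n, B, object$coefficients,
                         object$sigma, object$bounds)
  gbtm_e_step(L, object$pi)$loglik
}

#' @export
summary.gbtm <- function(object, ...) {
  J <- object$ngroups
  ct <- do.call(rbind, lapply(seq_len(J), function(j) {
    b <- object$coefficients[[j]]
    se <- object$coef_se[[j]]
    data.frame(group = j, term = paste0("t^", seq_along(b) - 1L),
               estimate = b, se = se, z = b / se)
  }))
  structure(list(fit = object, coef_table = ct, adequacy = adequacy(object)),
            class = "summary.gbtm")
}

#' @export
print.summary.gbtm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nPolynomial coefficients (intercept first):\n")
  ct <- x$coef_table
  ct$estimate <- signif(ct$estimate, digits)
  ct$se <- signif(ct$se, 3)
  ct$z <- round(ct$z, 2)
  print(ct, row.names = FALSE)
  cat("\n")
  print(x$adequacy)
  invisible(x)
}

#' Predicted group mean trajectories
#'
#' @param object a fitted `gbtm` model.
#' @param times numeric vector of hours; default the observed time grid.
#' @param groups which groups to evaluate; default all.
#' @param ... unused.
#' @return matrix with one row per time and one column per group (mmHg).
#' @export
predict.gbtm <- function(object, times = object$grid,
                         groups = seq_len(object$ngroups), ...) {
  out <- vapply(groups,
                function(j) trajectory_value(object$coefficients[[j]], times),
                numeric(length(times)))
  out <- matrix(out, nrow = length(times),
                dimnames = list(NULL, paste0("group", groups)))
  out
}

#' @export
fitted.gbtm <- function(object, type = c("modal", "weighted"), ...) {
  type <- match.arg(type)
  mf <- object$model
  M <- vapply(seq_len(object$ngroups),
              function(j) trajectory_value(object$coefficients[[j]], mf$time),
              numeric(nrow(mf)))
  M <- matrix(M, nrow = nrow(mf))
  if (type == "modal") {
    g <- object$assignments[as.character(mf$id)]
    M[cbind(seq_len(nrow(mf)), g)]
  } else {
    W <- object$posterior[as.character(mf$id), , drop = FALSE]
    rowSums(M * W)
  }
}

#' @export
residuals.gbtm <- function(object, type = c("modal", "weighted"), ...) {
  object$model$value - fitted(object, type = match.arg(type))
}

#' Plot fitted blood-pressure trajectories
#'
#' Draws the group mean trajectories over the observation window, optionally
#' over per-patient observed series ("spaghetti") coloured by modal group.
#'
#' @param x a fitted `gbtm` model.
#' @param spaghetti logical; overlay observed per-patient series.
#' @param col colours, one per group.
#' @param xlab,ylab,main usual graphical labels.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gbtm <- function(x, spaghetti = FALSE,
                      col = grDevices::hcl.colors(x$ngroups, "Dark 3"),
                      xlab = "Hours since start of thrombolysis",
                      ylab = "Blood pressure (mmHg)",
                      main = NULL, ...) {
  tt <- seq(min(x$grid), max(x$grid), length.out = 200L)
  M <- predict(x, times = tt)
  ylim <- range(M, if (spaghetti) x$model$value)
  graphics::matplot(tt, M, type = "l", lty = 1, lwd = 2.5, col = col,
                    xlab = xlab, ylab = ylab, ylim = ylim, main = main, ...)
  if (spaghetti) {
    for (pid in unique(x$model$id)) {
      sel <- x$model$id == pid
      graphics::lines(x$model$time[sel], x$model$value[sel],
                      col = grDevices::adjustcolor(col[x$assignments[[as.character(pid)]]], 0.25))
    }
    graphics::matlines(tt, M, lty = 1, lwd = 2.5, col = col)
  }
  graphics::legend("topright", bty = "n", lwd = 2.5, col = col,
                   legend = sprintf("group %d (%.1f%%)", seq_len(x$ngroups), 100 * x$pi))
  invisible(x)
}

#' Simulate cohorts from a fitted trajectory model
#'
#' Parametric simulation: draws group labels from the fitted membership
#' probabilities and series from the fitted polynomials plus iid normal noise
#' on the model's observed time grid.
#'
#' @param object a fitted `gbtm` model.
#' @param nsim number of replicate cohorts.
#' @param seed integer seed.
#' @param n number of patients per replicate; default the fitted cohort size.
#' @param ... unused.
#' @return a list of `nsim` data frames with columns `patient_id`, `time_h`,
#'   `value_mmhg`, `group` (true label).
#' @export
simulate.gbtm <- function(object, nsim = 1, seed = NULL,
                          n = object$n_patients, ...) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(as.integer(seed))
  }
  sig <- rep_len(object$sigma, object$ngroups)
  lapply(seq_len(nsim), function(r) {
    g <- sample.int(object$ngroups, n, replace = TRUE, prob = object$pi)
    nt <- length(object$grid)
    mu <- predict(object, times = object$grid)
    data.frame(
      patient_id = rep(sprintf("P%04d", seq_len(n)), each = nt),
      time_h = rep(object$grid, n),
      value_mmhg = as.vector(mu[, g]) + stats::rnorm(n * nt, 0, rep(sig[g], each = nt)),
      group = rep(g, each = nt))
  })
}
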
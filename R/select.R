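#' Select the number of trajectory groups
#'
#' Fits trajectory models over a range of group counts, screens each fit with
#' the adequacy rules (minimum group share, APPA), and selects the adequate
#' fit with the smallest BIC (AIC is reported; BIC is decisive). If no
#' candidate is adequate the best-BIC fit is returned flagged inadequate.
#'
#' Two shape policies are available. `"full"` fits every group at the maximum
#' polynomial degree (quartic by default). `"prune"` starts from the full fit
#' and backward-drops each group's highest-degree term while its Wald |z| is
#' below `z_keep`, refitting after each round, which yields the mixed
#' cubic/quartic shapes typical of published 24-h BP trajectory sets.
#'
#' @inheritParams gbtm
#' @param ngroups integer vector of candidate group counts, default `2:6`.
#' @param max_order maximum polynomial degree, default 4.
#' @param order_policy `"full"` or `"prune"`.
#' @param z_keep Wald |z| threshold below which a top-degree term is pruned
#'   (default 1.96).
#' @param min_share,min_appa adequacy thresholds passed to [adequacy()].
#' @return an object of class `gbtm_select`: `fits` (list of `gbtm` objects,
#'   named by J), `best` (the selected fit), `best_J`, `adequate` (logical for
#'   the selected fit) and `trace` (one row per candidate: J, orders, logLik,
#'   k, AIC, BIC, min share, min APPA, adequacy).
#' @export
gbtm_select <- function(formula, data, ngroups = 2:6, max_order = 4L,
                        order_policy = c("full", "prune"), z_keep = 1.96,
                        seed, min_share = 0.05, min_appa = 0.7,
                        bounds = c(-Inf, Inf), control = gbtm_control()) {
  if (missing(seed)) stop("'seed' is required")
  order_policy <- match.arg(order_policy)
  stopifnot(length(ngroups) >= 1L)
  fits <- list(); rows <- list()
  for (J in sort(unique(as.integer(ngroups)))) {
    fit <- gbtm(formula, data, ngroups = J, orders = max_order, seed = seed,
                bounds = bounds, control = control)
    if (order_policy == "prune") fit <- prune_orders(fit, formula, data, z_keep)
    adq <- adequacy(fit, min_share, min_appa)
    fits[[as.character(J)]] <- fit
    rows[[as.character(J)]] <- data.frame(
      J = J, orders = paste(fit$orders, collapse = "/"),
      logLik = fit$logLik, k = fit$k, aic = fit$aic, bic = fit$bic,
      min_share = min(adq$group_shares), min_appa = suppressWarnings(min(adq$appa)),
      adequate = adq$passes)
  }
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  pool <- if (any(trace$adequate)) which(trace$adequate) else seq_len(nrow(trace))
  pick <- pool[which.min(trace$bic[pool])]
  structure(list(fits = fits, best = fits[[pick]], best_J = trace$J[pick],
                 adequate = trace$adequate[pick], trace = trace,
                 order_policy = order_policy, call = match.call()),
            class = "gbtm_select")
}

## backward-drop each group's top-degree term while its Wald |z| < z_keep
prune_orders <- function(fit, formula, data, z_keep) {
  repeat {
    drop_j <- 0L; worst <- z_keep
    for (j in seq_len(fit$ngroups)) {
      if (fit$orders[j] == 0L) next
      b <- fit$coefficients[[j]]; se <- fit$coef_se[[j]]
      z <- abs(b[length(b)] / se[length(se)])
      if (is.finite(z) && z < worst) { worst <- z; drop_j <- j }
    }
    if (drop_j == 0L) return(fit)
    orders <- fit$orders
    orders[drop_j] <- orders[drop_j] - 1L
    fit <- gbtm(formula, data, ngroups = fit$ngroups, orders = orders,
                seed = fit$seed, bounds = fit$bounds, control = fit$control)
  }
}

#' @export
print.gbtm_select <- function(x, ...) {
  cat(sprintf("Trajectory-group selection over J = {%s} (%s shapes)\n",
              paste(x$trace$J, collapse = ", "), x$order_policy))
  tr <- x$trace
  tr$logLik <- round(tr$logLik, 1); tr$aic <- round(tr$aic, 1)
  tr$bic <- round(tr$bic, 1)
  tr$min_share <- round(tr$min_share, 3); tr$min_appa <- round(tr$min_appa, 3)
  print(tr, row.names = FALSE)
  cat(sprintf("Selected J = %d (%s)\n", x$best_J,
              if (x$adequate) "adequate, smallest BIC"
              else "no adequate candidate; best BIC, flagged inadequate"))
  invisible(x)
}
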
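#' Control parameters for GBTM estimation
#'
#' @param max_iter maximum EM iterations per start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param n_starts number of EM starts: one k-means-based start on per-patient
#'   (mean, slope) features plus `n_starts - 1` random-posterior starts.
#' @param sigma_min floor on the residual SD (mmHg), preventing degenerate
#'   likelihood spikes.
#' @param group_sd `"common"` (one residual SD shared by all groups, the
#'   standard censored-normal trajectory-model default) or `"group"`
#'   (group-specific SDs).
#' @param bic_n sample-size convention for the BIC penalty: number of
#'   `"patients"` (default) or of `"observations"`.
#' @return a list of class `gbtm_control`.
#' @export
gbtm_control <- function(max_iter = 500L, tol = 1e-8, n_starts = 10L,
                         sigma_min = 0.5, group_sd = c("common", "group"),
                         bic_n = c("patients", "observations")) {
  stopifnot(max_iter >= 1, tol > 0, n_starts >= 1, sigma_min > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_starts = as.integer(n_starts), sigma_min = sigma_min,
                 group_sd = match.arg(group_sd), bic_n = match.arg(bic_n)),
            class = "gbtm_control")
}

## formula of the form  value ~ time | id
parse_gbtm_formula <- function(formula, data) {
  if (!inherits(formula, "formula") || length(formula) != 3L)
    stop("'formula' must be two-sided, of the form value ~ time | id")
  rhs <- formula[[3L]]
  if (!(is.call(rhs) && identical(rhs[[1L]], as.name("|"))))
    stop("'formula' must separate time and patient id with '|': value ~ time | id")
  env <- environment(formula)
  y <- eval(formula[[2L]], data, env)
  t <- eval(rhs[[2L]], data, env)
  id <- eval(rhs[[3L]], data, env)
  if (length(y) != length(t) || length(y) != length(id))
    stop("value, time and id must have equal length")
  if (anyNA(y) || anyNA(t) || any(!is.finite(y)) || any(!is.finite(t)))
    stop("value and time must be finite and non-missing")
  id <- factor(id, levels = unique(id))
  ord <- order(as.integer(id), t)
  y <- as.numeric(y)[ord]; t <- as.numeric(t)[ord]; id <- id[ord]
  if (anyDuplicated(cbind(as.integer(id), t)))
    stop("duplicate (id, time) observations")
  list(y = y, t = t, id = as.integer(id), ids = levels(id), n = nlevels(id))
}

## per-patient-by-group log-likelihood matrix (n x J)
gbtm_group_loglik <- function(y, id, n, B, betas, sigma, bounds) {
  J <- length(betas)
  sig <- rep_len(sigma, J)
  L <- matrix(0, length(y), J)
  uncensored <- !is.finite(bounds[1L]) && !is.finite(bounds[2L])
  for (j in seq_len(J)) {
    b <- betas[[j]]
    mu <- drop(B[, seq_along(b), drop = FALSE] %*% b)
    if (uncensored) {
      L[, j] <- -log(sig[j]) - 0.9189385332046727 - 0.5 * ((y - mu) / sig[j])^2
    } else {
      L[, j] <- dcnorm(y, mu, sig[j], bounds[1L], bounds[2L], log = TRUE)
    }
  }
  rowsum(L, id)          # ids are 1..n so rows come back in patient order
}

## E-step: posteriors and observed-data log-likelihood
gbtm_e_step <- function(L, pi) {
  A <- sweep(L, 2L, log(pi), "+")
  m <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  lse <- m + log(rowSums(exp(A - m)))
  if (any(!is.finite(lse))) stop("likelihood underflow in E-step")
  list(W = exp(A - lse), loglik = sum(lse))
}

## M-step, closed form (valid when censoring is inactive)
gbtm_m_step_wls <- function(y, id, B, W, orders, sigma_min, group_sd) {
  J <- ncol(W)
  betas <- vector("list", J)
  rss <- sw <- numeric(J)
  for (j in seq_len(J)) {
    w <- W[id, j]
    X <- B[, seq_len(orders[j] + 1L), drop = FALSE]
    XtWX <- crossprod(X, X * w)
    b <- tryCatch(solve(XtWX, crossprod(X, y * w)),
                  error = function(e) stop("singular design in M-step: fewer distinct times than polynomial order + 1",
                                           call. = FALSE))
    betas[[j]] <- drop(b)
    r <- y - drop(X %*% b)
    rss[j] <- sum(w * r^2)
    sw[j] <- sum(w)
  }
  if (group_sd == "common") {
    sigma <- max(sqrt(sum(rss) / length(y)), sigma_min)
  } else {
    sigma <- pmax(sqrt(rss / pmax(sw, .Machine$double.eps)), sigma_min)
  }
  pi <- colMeans(W)
  list(betas = betas, sigma = sigma, pi = pi)
}

## expected complete-data log-likelihood (censored case), maximised numerically
gbtm_m_step_censored <- function(y, id, B, W, orders, bounds, sigma_min,
                                 group_sd, start) {
  J <- ncol(W)
  nsig <- if (group_sd == "common") 1L else J
  pack <- function(betas, sigma) c(unlist(betas), log(rep_len(sigma, nsig)))
  unpack <- function(par) {
    betas <- vector("list", J); pos <- 0L
    for (j in seq_len(J)) {
      betas[[j]] <- par[pos + seq_len(orders[j] + 1L)]
      pos <- pos + orders[j] + 1L
    }
    list(betas = betas, sigma = pmax(exp(par[pos + seq_len(nsig)]), sigma_min))
  }
  qfun <- function(par) {
    p <- unpack(par)
    sig <- rep_len(p$sigma, J)
    tot <- 0
    for (j in seq_len(J)) {
      b <- p$betas[[j]]
      mu <- drop(B[, seq_along(b), drop = FALSE] %*% b)
      tot <- tot + sum(W[id, j] *
                         dcnorm(y, mu, sig[j], bounds[1L], bounds[2L], log = TRUE))
    }
    tot
  }
  p0 <- pack(start$betas, start$sigma)
  opt <- stats::optim(p0, qfun, method = "BFGS",
                      control = list(fnscale = -1, maxit = 25L))
  par <- if (opt$value >= qfun(p0)) opt$par else p0
  p <- unpack(par)
  list(betas = p$betas, sigma = p$sigma, pi = colMeans(W))
}

## run EM from an initial posterior matrix
gbtm_em <- function(y, t, id, n, B, orders, bounds, control, W0) {
  uncensored <- !is.finite(bounds[1L]) && !is.finite(bounds[2L])
  W <- W0
  ll_old <- -Inf
  trace <- numeric(0)
  par <- NULL
  for (iter in seq_len(control$max_iter)) {
    par <- if (uncensored) {
      gbtm_m_step_wls(y, id, B, W, orders, control$sigma_min, control$group_sd)
    } else {
      warm <- gbtm_m_step_wls(y, id, B, W, orders, control$sigma_min, control$group_sd)
      gbtm_m_step_censored(y, id, B, W, orders, bounds, control$sigma_min,
                           control$group_sd, warm)
    }
    L <- gbtm_group_loglik(y, id, n, B, par$betas, par$sigma, bounds)
    es <- gbtm_e_step(L, par$pi)
    W <- es$W
    trace <- c(trace, es$loglik)
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) < control$tol * (abs(ll_old) + 0.1)) {
      return(list(par = par, W = W, loglik = es$loglik, trace = trace,
                  iterations = iter, converged = TRUE))
    }
    ll_old <- es$loglik
  }
  list(par = par, W = W, loglik = ll_old, trace = trace,
       iterations = control$max_iter, converged = FALSE)
}

## initial posteriors: k-means on (mean, slope) features and a quantile
## slicing of per-patient mean level, then random hard partitions
gbtm_starts <- function(y, t, id, n, J, n_starts) {
  soft <- function(cl) {
    W <- matrix(0.1 / max(J - 1L, 1L), n, J)
    W[cbind(seq_len(n), cl)] <- if (J == 1L) 1 else 0.9
    W / rowSums(W)
  }
  if (J == 1L) return(rep(list(matrix(1, n, 1L)), 1L))
  starts <- vector("list", n_starts)
  mean_i <- rowsum(y, id) / tabulate(id, n)
  tc <- t - rowsum(t, id)[id] / tabulate(id, n)[id]
  slope_i <- rowsum(tc * y, id) / pmax(rowsum(tc * tc, id), .Machine$double.eps)
  feats <- scale(cbind(mean_i, slope_i))
  feats[!is.finite(feats)] <- 0
  km <- tryCatch(stats::kmeans(feats, centers = J, nstart = 20L),
                 error = function(e) NULL)
  starts[[1L]] <- if (is.null(km)) soft(sample.int(J, n, replace = TRUE)) else soft(km$cluster)
  if (n_starts > 1L) {
    ## contiguous slices of the ranked per-patient mean level: the natural
    ## start for level-separated BP groups
    starts[[2L]] <- soft(as.integer(cut(rank(mean_i, ties.method = "first"),
                                        breaks = J, labels = FALSE)))
  }
  if (n_starts > 2L) {
    for (s in 3L:n_starts) starts[[s]] <- soft(sample.int(J, n, replace = TRUE))
  }
  starts
}

#' Fit a group-based trajectory model to longitudinal blood pressure
#'
#' Estimates a latent-class mixture of polynomial growth curves with
#' censored-normal residuals by maximum likelihood (EM). Each of the
#' `ngroups` latent groups follows its own polynomial mean trajectory in time;
#' group membership probabilities are an intercept-only multinomial logit;
#' residuals share a common SD by default. Groups are labelled in ascending
#' order of their mean trajectory value over the observed time grid, so labels
#' are invariant to initialisation.
#'
#' @param formula a two-sided formula `value ~ time | id` naming the measured
#'   pressure (mmHg), the time since infusion start (hours) and the patient
#'   identifier in `data`.
#' @param data a data frame in long format.
#' @param ngroups number of latent trajectory groups (J >= 1).
#' @param orders polynomial degree per group, scalar or length-`ngroups`
#'   vector, each in 0..4. Default 4 (quartic), the most flexible shape used
#'   for 24-h BP courses.
#' @param seed integer seed controlling the EM starts; required so fits are
#'   reproducible.
#' @param bounds length-2 censoring bounds of the censored-normal outcome
#'   distribution; default `c(-Inf, Inf)` (inactive — observed BP does not sit
#'   on a scale bound in this application).
#' @param control a [gbtm_control()] list.
#' @return an object of class `"gbtm"` with components `coefficients` (list of
#'   per-group polynomial coefficients, intercept first), `coef_se`, `sigma`,
#'   `pi` (group membership probabilities), `theta` (membership logits,
#'   group 1 fixed at 0), `posterior` (n x J matrix), `assignments` (modal
#'   group per patient), `logLik`, `k`, `aic`, `bic`, `loglik_trace`, and the
#'   model frame. Methods: `print`, `summary`, `coef`, `logLik`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`, plus [adequacy()] and
#'   [posterior_matrix()].
#' @examples
#' coh <- simulate_bp_cohort(n = 60, seed = 1,
#'                           config = cohort_config(channels = list(
#'                             SBP = channel_spec(
#'                               shapes = list(c(120, 0), c(160, 0)),
#'                               probs = c(0.5, 0.5), sigma = 5)),
#'                             outcomes = NULL))
#' fit <- gbtm(value_mmhg ~ time_h | patient_id, data = coh$bp,
#'             ngroups = 2, orders = 0, seed = 1,
#'             control = gbtm_control(n_starts = 2))
#' fit
#' @export
gbtm <- function(formula, data, ngroups, orders = 4L, seed,
                 bounds = c(-Inf, Inf), control = gbtm_control()) {
  if (missing(seed)) stop("'seed' is required (reproducible EM starts)")
  ngroups <- as.integer(ngroups)
  stopifnot(ngroups >= 1L, length(bounds) == 2L, bounds[1L] < bounds[2L])
  orders <- as.integer(rep_len(orders, ngroups))
  if (any(orders < 0L | orders > 4L)) stop("'orders' must lie in 0..4")
  d <- parse_gbtm_formula(formula, data)
  nt <- length(unique(d$t))
  if (nt < max(orders) + 1L)
    stop("need at least max(orders)+1 distinct observation times")
  obs_per <- tabulate(d$id, d$n)
  if (any(obs_per < max(orders) + 1L))
    stop("every patient needs at least max(orders)+1 observations")

  B <- outer(d$t, 0:max(orders), `^`)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  starts <- gbtm_starts(d$y, d$t, d$id, d$n, ngroups, control$n_starts)
  best <- NULL; n_collapsed <- 0L
  for (W0 in starts) {
    res <- tryCatch(gbtm_em(d$y, d$t, d$id, d$n, B, orders, bounds, control, W0),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (min(colSums(res$W)) < 1) { n_collapsed <- n_collapsed + 1L; next }
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best))
    stop("no EM start converged without a collapsed group; try different 'seed', fewer groups, or more starts")
  if (n_collapsed > 0L && n_collapsed == length(starts) - 1L && ngroups > 1L)
    warning(sprintf("%d of %d EM starts collapsed a group", n_collapsed, length(starts)))

  ## relabel groups by ascending mean trajectory over the observed grid
  grid <- sort(unique(d$t))
  Bg <- outer(grid, 0:max(orders), `^`)
  gm <- vapply(best$par$betas, function(b)
    mean(drop(Bg[, seq_along(b), drop = FALSE] %*% b)), numeric(1))
  perm <- order(gm)
  betas <- best$par$betas[perm]
  orders <- orders[perm]
  pi <- best$par$pi[perm]
  sigma <- if (length(best$par$sigma) > 1L) best$par$sigma[perm] else best$par$sigma
  W <- best$W[, perm, drop = FALSE]
  theta <- log(pi / pi[1L])

  ## Wald SEs of the polynomial coefficients from the converged weighted LS
  sig <- rep_len(sigma, ngroups)
  coef_se <- vector("list", ngroups)
  for (j in seq_len(ngroups)) {
    X <- B[, seq_len(orders[j] + 1L), drop = FALSE]
    XtWX <- crossprod(X, X * W[d$id, j])
    v <- tryCatch(diag(solve(XtWX)) * sig[j]^2, error = function(e) rep(NA_real_, ncol(X)))
    coef_se[[j]] <- sqrt(pmax(v, 0))
  }

  k <- sum(orders + 1L) + (ngroups - 1L) + length(sigma)
  n_ic <- if (control$bic_n == "patients") d$n else length(d$y)
  ic <- information_criteria(best$loglik, k, n_ic)

  assignments <- max.col(W, ties.method = "first")
  names(assignments) <- d$ids
  rownames(W) <- d$ids
  names(betas) <- names(coef_se) <- paste0("group", seq_len(ngroups))

  structure(list(
    coefficients = betas, coef_se = coef_se, sigma = sigma, pi = pi,
    theta = theta, ngroups = ngroups, orders = orders, bounds = bounds,
    logLik = best$loglik, k = k, aic = ic[["aic"]], bic = ic[["bic"]],
    posterior = W, assignments = assignments,
    loglik_trace = best$trace, iterations = best$iterations,
    converged = best$converged, collapsed_starts = n_collapsed,
    n_patients = d$n, n_obs = length(d$y), grid = grid,
    model = data.frame(id = d$ids[d$id], time = d$t, value = d$y),
    control = control, seed = as.integer(seed),
    call = match.call(), formula = formula
  ), class = "gbtm")
}

#' Information criteria for a fitted trajectory model
#'
#' Positive-form AIC and BIC (smaller is better):
#' `aic = 2k - 2 logLik`, `bic = k log(n) - 2 logLik`.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of free parameters.
#' @param n sample size entering the BIC penalty (number of patients by
#'   convention here).
#' @return named numeric vector `c(aic, bic)`.
#' @export
information_criteria <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  c(aic = 2 * k - 2 * loglik, bic = k * log(n) - 2 * loglik)
}

#' Posterior group-membership matrix
#'
#' Returns the per-patient posterior membership probabilities and modal
#' assignments of a fitted trajectory model. Rows sum to one; the modal
#' assignment is the arg-max of the row with ties broken toward the lowest
#' group label.
#'
#' @param object a fitted `gbtm` model.
#' @return a list with `probs` (n x J matrix, rownames = patient ids) and
#'   `assignments` (named integer vector).
#' @export
posterior_matrix <- function(object) {
  stopifnot(inherits(object, "gbtm"))
  list(probs = object$posterior, assignments = object$assignments)
}

#' Classification adequacy of a trajectory model
#'
#' Checks the two standard adequacy rules for a group-based trajectory model:
#' every group's modal-assignment share must be at least `min_share` (default
#' 5\%), and every group's average posterior probability of assignment (APPA)
#' among its assigned members must exceed `min_appa` (default 0.7).
#'
#' @param object a fitted `gbtm` model.
#' @param min_share minimum modal share per group (inclusive).
#' @param min_appa minimum APPA per group (exclusive).
#' @return an object of class `gbtm_adequacy`: group shares, APPA values and
#'   pass flags. An empty group yields share 0 (failing the share rule), not
#'   an error.
#' @export
adequacy <- function(object, min_share = 0.05, min_appa = 0.7) {
  stopifnot(inherits(object, "gbtm"))
  J <- object$ngroups
  n <- object$n_patients
  cl <- object$assignments
  shares <- tabulate(cl, J) / n
  appa <- vapply(seq_len(J), function(j) {
    in_j <- cl == j
    if (!any(in_j)) return(NA_real_)
    mean(object$posterior[in_j, j])
  }, numeric(1))
  passes_min_share <- all(shares >= min_share)
  passes_appa <- all(!is.na(appa) & appa > min_appa)
  structure(list(group_shares = shares, appa = appa,
                 min_share = min_share, min_appa = min_appa,
                 passes_min_share = passes_min_share,
                 passes_appa = passes_appa,
                 passes = passes_min_share && passes_appa),
            class = "gbtm_adequacy")
}

#' @export
print.gbtm_adequacy <- function(x, ...) {
  cat("Trajectory-group adequacy\n")
  tab <- data.frame(group = seq_along(x$group_shares),
                    share = round(x$group_shares, 3),
                    appa = round(x$appa, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("min share >= %.2f: %s;  APPA > %.2f: %s;  overall: %s\n",
              x$min_share, if (x$passes_min_share) "pass" else "FAIL",
              x$min_appa, if (x$passes_appa) "pass" else "FAIL",
              if (x$passes) "adequate" else "inadequate"))
  invisible(x)
}
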
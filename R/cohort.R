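#' The 24-h post-thrombolysis BP measurement grid
#'
#' Builds the standard bedside monitoring schedule after intravenous
#' alteplase: a reading at infusion start, then every 15 min for 2 h, every
#' 30 min for the next 6 h, and hourly for the remaining 16 h — 37 readings
#' over 24 h with the default arguments.
#'
#' @param intervals reading interval of each segment (hours).
#' @param durations duration of each segment (hours), same length.
#' @param start time of the first reading (hours), default 0.
#' @return strictly increasing numeric vector of reading times.
#' @examples
#' length(measurement_grid())  # 37
#' measurement_grid(intervals = 1, durations = 2)  # 0 1 2
#' @export
measurement_grid <- function(intervals = c(0.25, 0.5, 1),
                             durations = c(2, 6, 16), start = 0) {
  if (length(intervals) != length(durations))
    stop("'intervals' and 'durations' must have equal length")
  if (any(intervals <= 0) || any(durations <= 0) || any(intervals > durations))
    stop("invalid schedule: need 0 < interval <= duration in every segment")
  times <- start
  for (s in seq_along(intervals)) {
    seg_end <- times[length(times)] + durations[s]
    times <- c(times, seq(times[length(times)] + intervals[s], seg_end,
                          by = intervals[s]))
  }
  if (any(diff(times) <= 0)) stop("schedule segments overlap")
  times
}

#' Reference SBP trajectory set
#'
#' The package's shipped five-group systolic reference trajectories for the
#' 24 h after thrombolysis: per-group polynomial coefficients (intercept
#' first, mmHg over hours), membership probabilities and descriptive labels,
#' spanning slow drop-low through continuous fluctuation-very high patterns.
#' These are the default generating truth of [simulate_bp_cohort()].
#'
#' @return a `channel_spec` list: `shapes`, `probs`, `sigma`, `labels`.
#' @export
default_sbp_groups <- function() {
  channel_spec(
    shapes = list(c(115.677, -4.632, 0.690, -0.038, 0.0007),
                  c(136.173, -5.822, 0.749, -0.039, 0.0007),
                  c(151.043, -5.849, 0.701, -0.033, 0.0006),
                  c(165.549, -3.639, 0.232, -0.004),
                  c(174.543, -2.773, 0.223, -0.005)),
    probs = c(0.062, 0.218, 0.348, 0.240, 0.132),
    sigma = 8,
    labels = c("slow drop-low", "rapid drop-low", "rapid drop-medium",
               "rapid drop-high", "continuous fluctuation-very high"))
}

#' Reference DBP trajectory set
#'
#' Shipped four-group diastolic reference trajectories; see
#' [default_sbp_groups()].
#'
#' @return a `channel_spec` list.
#' @export
default_dbp_groups <- function() {
  channel_spec(
    shapes = list(c(72.943, -3.199, 0.379, -0.019, 0.0004),
                  c(80.997, -2.759, 0.326, -0.015, 0.0003),
                  c(92.696, -2.545, 0.173, -0.003),
                  c(103.607, -4.175, 0.601, -0.031, 0.0005)),
    probs = c(0.193, 0.408, 0.319, 0.080),
    sigma = 6,
    labels = c("rapid drop-low", "slow drop-medium", "rapid drop-high",
               "continuous fluctuation-very high"))
}

#' Channel specification for the cohort generator
#'
#' @param shapes list of per-group polynomial coefficient vectors (intercept
#'   first).
#' @param probs group membership probabilities, summing to 1.
#' @param sigma residual SD (mmHg).
#' @param labels optional group labels.
#' @return a `channel_spec` list.
#' @export
channel_spec <- function(shapes, probs, sigma, labels = NULL) {
  stopifnot(length(shapes) == length(probs), sigma > 0,
            abs(sum(probs) - 1) < 1e-8, all(probs > 0))
  list(shapes = shapes, probs = probs / sum(probs), sigma = sigma,
       labels = labels %||% paste("group", seq_along(shapes)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Outcome specification for the cohort generator
#'
#' Defines a binary outcome generated from a logistic model on trajectory
#' group: `logit P(Y=1) = alpha + log OR[g] (+ log OR_glu * (glucose - mean))`,
#' with the intercept `alpha` calibrated so the marginal event rate matches
#' `prevalence` (see [calibrate_intercept()]).
#'
#' @param channel `"SBP"` or `"DBP"`: which channel's groups drive the
#'   outcome.
#' @param or per-group odds ratios relative to the reference group (which has
#'   OR 1); length = number of groups of that channel.
#' @param prevalence target marginal event probability in (0, 1).
#' @param glucose_or optional per-mmol/L glucose odds ratio; glucose enters
#'   centred at its generating mean so the calibrated prevalence is preserved.
#' @return an `outcome_spec` list.
#' @export
outcome_spec <- function(channel = "SBP", or, prevalence, glucose_or = NULL) {
  stopifnot(channel %in% c("SBP", "DBP"), all(or > 0),
            prevalence > 0, prevalence < 1)
  list(channel = channel, or = or, prevalence = prevalence,
       glucose_or = glucose_or)
}

#' Cohort generator configuration
#'
#' Shipped defaults reproduce the generating conditions the package validates
#' against: the five-group SBP and four-group DBP reference trajectories with
#' their membership probabilities, residual SDs of 8 (SBP) and 6 (DBP) mmHg,
#' the 37-point 24-h measurement grid, iid measurement noise, demographic
#' covariates (age ~ N(62.49, 11.79^2) years, 72.8\% male,
#' glucose ~ N(6.8, 3^2) mmol/L truncated at 2.5), uniformly distributed
#' onset clock times, and three binary outcomes driven by SBP group with
#' unadjusted odds ratios of the reference association set: early
#' neurological deterioration (END, marginal 19.0\%), early neurological
#' improvement (ENI, 37.1\%) and unfavourable 3-month outcome
#' (mRS 3-6, 31.4\%).
#'
#' @param channels named list of [channel_spec()]s (`SBP`, `DBP`).
#' @param grid measurement times, default [measurement_grid()].
#' @param noise `"iid"` or `"ar1"`; `rho` is the lag-1 correlation of the
#'   stationary AR(1) noise (marginal SD kept at the channel sigma).
#' @param outcomes named list of [outcome_spec()]s.
#' @param covariates list with `age_mean`, `age_sd`, `p_male`, `glucose_mean`,
#'   `glucose_sd`.
#' @param outcome_mode `"independent"` (each outcome drawn independently given
#'   covariates) or `"exclusive"` (END/ENI drawn as a joint categorical
#'   END / ENI / neither, since a patient cannot deteriorate and improve at
#'   once; preserves the END marginal, slightly shrinks ENI).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(channels = list(SBP = default_sbp_groups(),
                                          DBP = default_dbp_groups()),
                          grid = measurement_grid(),
                          noise = "iid", rho = 0.6,
                          outcomes = default_outcomes(),
                          covariates = list(age_mean = 62.49, age_sd = 11.79,
                                            p_male = 0.728,
                                            glucose_mean = 6.8, glucose_sd = 3),
                          outcome_mode = c("independent", "exclusive")) {
  noise <- match.arg(noise, c("iid", "ar1"))
  stopifnot(all(diff(grid) > 0), rho > -1, rho < 1)
  if (is.null(outcomes)) outcomes <- list()
  for (oc in outcomes) {
    ngr <- length(channels[[oc$channel]]$probs)
    if (length(oc$or) != ngr)
      stop("outcome OR vector length must match the group count of its channel")
  }
  structure(list(channels = channels, grid = grid, noise = noise, rho = rho,
                 outcomes = outcomes, covariates = covariates,
                 outcome_mode = match.arg(outcome_mode)),
            class = "cohort_config")
}

#' Default outcome specifications
#'
#' Unadjusted (crude) per-group odds ratios of the reference association set,
#' keyed to SBP trajectory group with group 3 (rapid drop-medium) as
#' reference, and the reference marginal prevalences: END 19.0\%, ENI 37.1\%,
#' unfavourable mRS 31.4\%.
#'
#' @return named list of [outcome_spec()]s (`end`, `eni`, `mrs`).
#' @export
default_outcomes <- function() {
  list(end = outcome_spec("SBP", c(0.263, 1.140, 1, 1.507, 2.852), 0.190),
       eni = outcome_spec("SBP", c(0.841, 1.152, 1, 0.379, 0.288), 0.371),
       mrs = outcome_spec("SBP", c(0.963, 1.251, 1, 2.228, 2.883), 0.314))
}

#' Calibrate a logistic intercept to a target marginal prevalence
#'
#' Solves \eqn{\sum_j \pi_j \mathrm{expit}(\alpha + \log OR_j) = p} for the
#' intercept \eqn{\alpha} by monotone one-dimensional root finding (to
#' absolute tolerance 1e-10). Because expit is bounded and strictly
#' increasing a root always exists and is unique.
#'
#' @param or per-group odds ratios (reference group OR 1).
#' @param probs group membership probabilities.
#' @param target target marginal prevalence in (0, 1).
#' @return scalar intercept on the logit scale.
#' @examples
#' calibrate_intercept(rep(1, 3), c(.2, .5, .3), 0.19)  # qlogis(0.19)
#' @export
calibrate_intercept <- function(or, probs, target) {
  stopifnot(length(or) == length(probs), target > 0, target < 1,
            all(or > 0), all(probs >= 0))
  probs <- probs / sum(probs)
  f <- function(a) sum(probs * stats::plogis(a + log(or))) - target
  lo <- -40; hi <- 40
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

## stationary AR(1) noise, marginal sd `sd`, lag-1 correlation rho, by index
ar1_noise <- function(n_series, n_time, sd, rho) {
  z <- matrix(stats::rnorm(n_series * n_time), n_time, n_series)
  e <- z
  if (n_time > 1L) for (k in 2L:n_time) e[k, ] <- rho * e[k - 1L, ] + sqrt(1 - rho^2) * z[k, ]
  e * sd
}

#' Simulate a synthetic post-thrombolysis cohort
#'
#' Generates a cohort with the statistical structure the trajectory analysis
#' assumes: latent SBP/DBP trajectory group labels, serial BP measurements on
#' the monitoring grid (group polynomial mean plus noise), baseline
#' covariates, onset clock times, and binary outcomes from group-driven
#' logistic models with intercepts calibrated to target marginal prevalences.
#' All randomness flows from `seed`; reruns are bit-identical.
#'
#' @param n number of patients.
#' @param seed integer seed (required).
#' @param config a [cohort_config()].
#' @param series logical; generate the BP series (set `FALSE` for large
#'   outcome-only simulations).
#' @return list with `bp` (long data frame `patient_id`, `channel`, `time_h`,
#'   `value_mmhg`; `NULL` if `series = FALSE`), `covariates` (`patient_id`,
#'   `age`, `sex` (1 = male), `glucose`, `onset_clock`), `outcomes`
#'   (`patient_id`, `end_24h`, `eni_24h`, `mrs_unfavorable`) and `truth`
#'   (true group labels per channel, calibrated intercepts, the config).
#' @export
simulate_bp_cohort <- function(n = 353, seed, config = cohort_config(),
                               series = TRUE) {
  if (missing(seed)) stop("'seed' is required for a reproducible cohort")
  stopifnot(inherits(config, "cohort_config"), n >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  ids <- sprintf("P%06d", seq_len(n))
  labels <- lapply(config$channels, function(ch)
    sample.int(length(ch$probs), n, replace = TRUE, prob = ch$probs))

  cv <- config$covariates
  covariates <- data.frame(
    patient_id = ids,
    age = stats::rnorm(n, cv$age_mean, cv$age_sd),
    sex = stats::rbinom(n, 1, cv$p_male),
    glucose = pmax(stats::rnorm(n, cv$glucose_mean, cv$glucose_sd), 2.5),
    onset_clock = stats::runif(n, 0, 24))

  bp <- NULL
  if (series) {
    nt <- length(config$grid)
    pieces <- lapply(names(config$channels), function(chn) {
      ch <- config$channels[[chn]]
      g <- labels[[chn]]
      mu <- vapply(ch$shapes, trajectory_value, numeric(nt), t = config$grid)
      noise <- if (config$noise == "iid") {
        matrix(stats::rnorm(nt * n, 0, ch$sigma), nt, n)
      } else {
        ar1_noise(n, nt, ch$sigma, config$rho)
      }
      data.frame(patient_id = rep(ids, each = nt), channel = chn,
                 time_h = rep(config$grid, n),
                 value_mmhg = as.vector(mu[, g] + noise))
    })
    bp <- do.call(rbind, pieces)
  }

  outcomes <- NULL
  alphas <- numeric(0)
  if (length(config$outcomes)) {
    alphas <- vapply(config$outcomes, function(oc)
      calibrate_intercept(oc$or, config$channels[[oc$channel]]$probs,
                          oc$prevalence), numeric(1))
    pmat <- vapply(names(config$outcomes), function(nm) {
      oc <- config$outcomes[[nm]]
      lp <- alphas[[nm]] + log(oc$or)[labels[[oc$channel]]]
      if (!is.null(oc$glucose_or))
        lp <- lp + log(oc$glucose_or) * (covariates$glucose - cv$glucose_mean)
      stats::plogis(lp)
    }, numeric(n))
    pmat <- matrix(pmat, nrow = n, dimnames = list(NULL, names(config$outcomes)))

    draw <- matrix(stats::runif(n * ncol(pmat)), n)
    y <- (draw < pmat) * 1L
    if (config$outcome_mode == "exclusive" &&
        all(c("end", "eni") %in% colnames(pmat))) {
      ## joint categorical END / ENI / neither: END keeps its marginal,
      ## ENI is only drawn among non-END patients
      y[, "eni"] <- ifelse(y[, "end"] == 1L, 0L, y[, "eni"])
    }
    outcomes <- data.frame(patient_id = ids)
    std <- c(end = "end_24h", eni = "eni_24h", mrs = "mrs_unfavorable")
    for (nm in colnames(y)) {
      outcomes[[if (nm %in% names(std)) std[[nm]] else nm]] <- y[, nm]
    }
  }

  list(bp = bp, covariates = covariates, outcomes = outcomes,
       truth = list(labels = data.frame(patient_id = ids,
                                        SBP = labels$SBP %||% NA,
                                        DBP = labels$DBP %||% NA),
                    intercepts = alphas, config = config, seed = as.integer(seed)))
}
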
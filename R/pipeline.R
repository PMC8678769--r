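## structural validation shared by the readers and bp_parameter_table
check_bp_long <- function(bp) {
  need <- c("patient_id", "channel", "time_h", "value_mmhg")
  miss <- setdiff(need, names(bp))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  invisible(bp)
}

#' Read a long-format blood-pressure CSV
#'
#' Reads and validates serial BP measurements with header
#' `patient_id,channel,time_h,value_mmhg`. Rows are sorted by patient,
#' channel and time; non-numeric or non-positive pressures, missing values
#' and duplicated (patient, channel, time) rows are rejected with the
#' offending row number.
#'
#' @param path CSV file path.
#' @return validated long data frame.
#' @export
read_bp_long <- function(path) {
  bp <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_bp_long(bp)
  bad <- which(!is.finite(suppressWarnings(as.numeric(bp$value_mmhg))) |
                 suppressWarnings(as.numeric(bp$value_mmhg)) <= 0)
  if (length(bad))
    stop("non-numeric or non-positive value_mmhg at data row ", bad[1L])
  bad_t <- which(!is.finite(suppressWarnings(as.numeric(bp$time_h))))
  if (length(bad_t)) stop("non-numeric time_h at data row ", bad_t[1L])
  bp$value_mmhg <- as.numeric(bp$value_mmhg)
  bp$time_h <- as.numeric(bp$time_h)
  dup <- which(duplicated(bp[c("patient_id", "channel", "time_h")]))
  if (length(dup))
    stop("duplicate (patient_id, channel, time_h) at data row ", dup[1L])
  bp[order(bp$patient_id, bp$channel, bp$time_h), , drop = FALSE]
}

#' Write a fitted model's trajectory coefficients as CSV
#'
#' One row per group: label, membership probability, modal share and the
#' polynomial coefficients intercept-first (padded with `NA` above the
#' group's degree), mirroring the per-group polynomial layout of published
#' trajectory sets.
#'
#' @param fit a `gbtm` object.
#' @param path output CSV path.
#' @return the written data frame, invisibly.
#' @export
write_trajectory_csv <- function(fit, path) {
  maxd <- max(fit$orders)
  rows <- lapply(seq_len(fit$ngroups), function(j) {
    b <- rep(NA_real_, maxd + 1L)
    b[seq_along(fit$coefficients[[j]])] <- fit$coefficients[[j]]
    cbind(data.frame(group = j, pi = fit$pi[j],
                     share = sum(fit$assignments == j) / fit$n_patients),
          as.data.frame(as.list(stats::setNames(b, paste0("b", 0:maxd)))))
  })
  out <- do.call(rbind, rows)
  out[-1L] <- lapply(out[-1L], round, digits = 6)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

## round every numeric leaf to 1e-6 for reproducible report diffs
round_rec <- function(x, digits = 6) {
  if (is.list(x)) lapply(x, round_rec, digits = digits)
  else if (is.numeric(x)) round(x, digits)
  else x
}

#' Serialise a fitted trajectory model to JSON
#'
#' @param fit a `gbtm` object.
#' @param path output path; `NULL` returns the JSON string.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_model_json <- function(fit, path = NULL) {
  adq <- adequacy(fit)
  obj <- round_rec(list(
    ngroups = fit$ngroups, orders = fit$orders,
    coefficients = fit$coefficients, sigma = fit$sigma, pi = fit$pi,
    theta = fit$theta, logLik = fit$logLik, k = fit$k,
    aic = fit$aic, bic = fit$bic, n_patients = fit$n_patients,
    seed = fit$seed, converged = fit$converged,
    adequacy = list(group_shares = adq$group_shares, appa = adq$appa,
                    passes = adq$passes)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Run the full trajectory-outcome analysis pipeline
#'
#' Ties the stages together: (optionally) simulate or read a cohort, select
#' and fit the trajectory model per channel, assign patients to groups,
#' compute the classic BP parameter table, fit the nested outcome models
#' (crude, demographic-adjusted, fully adjusted with screened covariates) for
#' every trajectory group and outcome, compute predictor AUCs, and write all
#' artifacts to `out_dir` (CSV tables plus a JSON report embedding the
#' configuration and seed).
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed (required).
#' @param bp long BP data frame or path to a CSV; `NULL` simulates a cohort.
#' @param covariates,outcomes data frames matching the simulated layout; only
#'   used with external `bp`.
#' @param n cohort size when simulating.
#' @param config [cohort_config()] for simulation.
#' @param ngroups named list of candidate group counts per channel.
#' @param order_policy shape policy for [gbtm_select()].
#' @param reference named list of reference group labels per channel.
#' @param control [gbtm_control()].
#' @return invisibly, a list with the per-channel selections, group
#'   assignments, BP parameter table, association and AUC tables, and the
#'   report path.
#' @export
run_bp_pipeline <- function(out_dir, seed, bp = NULL, covariates = NULL,
                            outcomes = NULL, n = 353,
                            config = cohort_config(),
                            ngroups = list(SBP = 2:6, DBP = 2:6),
                            order_policy = "full",
                            reference = list(SBP = 3, DBP = 2),
                            control = gbtm_control()) {
  if (missing(seed)) stop("'seed' is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulated <- is.null(bp)
  if (simulated) {
    coh <- simulate_bp_cohort(n = n, seed = seed, config = config)
    bp <- coh$bp; covariates <- coh$covariates; outcomes <- coh$outcomes
    utils::write.csv(coh$truth$labels, file.path(out_dir, "truth_labels.csv"),
                     row.names = FALSE)
  } else if (is.character(bp)) {
    bp <- read_bp_long(bp)
  } else {
    check_bp_long(bp)
  }
  utils::write.csv(bp, file.path(out_dir, "bp_long.csv"), row.names = FALSE)
  if (!is.null(covariates))
    utils::write.csv(covariates, file.path(out_dir, "covariates.csv"), row.names = FALSE)
  if (!is.null(outcomes))
    utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"), row.names = FALSE)

  selections <- list(); assignments <- list()
  for (chn in intersect(names(ngroups), unique(bp$channel))) {
    sel <- gbtm_select(value_mmhg ~ time_h | patient_id,
                       data = bp[bp$channel == chn, , drop = FALSE],
                       ngroups = ngroups[[chn]], order_policy = order_policy,
                       seed = seed, control = control)
    selections[[chn]] <- sel
    assignments[[chn]] <- sel$best$assignments
    write_trajectory_csv(sel$best, file.path(out_dir, paste0("trajectories_", chn, ".csv")))
    write_model_json(sel$best, file.path(out_dir, paste0("model_", chn, ".json")))
  }

  onset <- 8
  if (!is.null(covariates) && "onset_clock" %in% names(covariates))
    onset <- stats::setNames(covariates$onset_clock, covariates$patient_id)
  partab <- bp_parameter_table(bp, onset = onset)
  utils::write.csv(round_df(partab), file.path(out_dir, "bp_parameters.csv"),
                   row.names = FALSE)

  assoc <- auc_tab <- NULL
  if (!is.null(outcomes)) {
    ocols <- setdiff(names(outcomes), "patient_id")
    covs <- if (is.null(covariates)) NULL
            else covariates[match(outcomes$patient_id, covariates$patient_id),
                            setdiff(names(covariates), c("patient_id", "onset_clock")),
                            drop = FALSE]
    arows <- list(); aucrows <- list()
    for (chn in names(assignments)) {
      g <- assignments[[chn]][as.character(outcomes$patient_id)]
      ref <- min(max(1, reference[[chn]] %||% 1), max(g))
      for (oc in ocols) {
        y <- outcomes[[oc]]
        res <- trajectory_association(g, y, reference = ref, covariates = covs)
        res <- cbind(data.frame(channel = chn, outcome = oc), res)
        arows[[paste(chn, oc)]] <- res
        aucrows[[paste(chn, oc)]] <- cbind(
          data.frame(predictor = paste0(chn, "_trajectory"), outcome = oc),
          roc_auc(g, y))
      }
    }
    assoc <- do.call(rbind, arows)
    auc_tab <- do.call(rbind, aucrows)
    rownames(assoc) <- rownames(auc_tab) <- NULL
    utils::write.csv(round_df(assoc), file.path(out_dir, "associations.csv"),
                     row.names = FALSE)
    utils::write.csv(round_df(auc_tab), file.path(out_dir, "auc.csv"),
                     row.names = FALSE)
  }

  report <- round_rec(list(
    seed = as.integer(seed), simulated = simulated,
    n_patients = length(unique(bp$patient_id)),
    channels = lapply(selections, function(s)
      list(best_J = s$best_J, adequate = s$adequate,
           trace = lapply(seq_len(nrow(s$trace)), function(i) as.list(s$trace[i, ])))),
    outputs = list.files(out_dir)))
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "report.json"))
  invisible(list(selections = selections, assignments = assignments,
                 bp_parameters = partab, associations = assoc, auc = auc_tab,
                 report_path = file.path(out_dir, "report.json")))
}

round_df <- function(d, digits = 6) {
  d[] <- lapply(d, function(x) if (is.numeric(x)) round(x, digits) else x)
  d
}
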
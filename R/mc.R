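#' Classify free parameters into the twelve Monte-Carlo types
#'
#' Every free parameter of an LS-COM template belongs to exactly one of
#' twelve types used for aggregated bias reporting: eight from the between
#' part (state, common method, and method factor loadings, Level-2 latent
#' covariances, latent means, intercepts, Level-2 latent variances, Level-2
#' residual variances) and four from the within part (unique method factor
#' loadings, Level-1 latent variances and covariances, Level-1 residual
#' variances).
#'
#' @param template A model template (or an `lscom_fit`).
#' @return Named character vector mapping parameter label to type.
#' @export
parameter_type_map <- function(template) {
  if (inherits(template, "lscom_fit")) {
    est <- template$estimates
    return(setNames(est$type, est$label))
  }
  cm <- compile_model(template)
  setNames(cm$nat$type, cm$nat$label)
}

#' Aggregated absolute relative parameter bias
#'
#' For each parameter, the mean estimate across replications is compared to
#' its true value as `|mean(est) - true| / |true|`; values are then averaged
#' within each parameter type.  Parameters with a true value of zero are
#' excluded (the ratio is undefined there) with a note.
#'
#' @param estimates_by_rep Matrix of estimates, replications in rows,
#'   parameters (named columns) in columns.
#' @param truth Named vector of true values.
#' @param type_map Named character vector from [parameter_type_map()].
#' @return Named numeric vector of per-type bias values (proportions).
#' @export
peb <- function(estimates_by_rep, truth, type_map) {
  stopifnot(is.matrix(estimates_by_rep))
  labs <- colnames(estimates_by_rep)
  truth <- truth[labs]
  types <- type_map[labs]
  keep <- !is.na(truth) & truth != 0
  if (any(!keep)) {
    message(sum(!keep), " parameter(s) with true value 0 excluded from ",
            "parameter-bias aggregation")
  }
  M <- colMeans(estimates_by_rep[, keep, drop = FALSE])
  rel <- abs(M - truth[keep]) / abs(truth[keep])
  out <- tapply(rel, types[keep], mean)
  setNames(as.numeric(out), names(out))
}

#' Aggregated absolute relative standard-error bias
#'
#' For each parameter, the mean reported standard error across replications
#' is compared to the empirical standard deviation of its estimates
#' (denominator `n_reps - 1`) as `|mean(SE) - SD| / SD`; values are averaged
#' within parameter type.  Parameters whose empirical SD is zero are
#' excluded with a note.
#'
#' @param ses_by_rep Matrix of reported standard errors (replications x
#'   parameters).
#' @param estimates_by_rep Matching matrix of estimates.
#' @param type_map Named character vector from [parameter_type_map()].
#' @return Named numeric vector of per-type SE bias values (proportions).
#' @export
seb <- function(ses_by_rep, estimates_by_rep, type_map) {
  stopifnot(is.matrix(ses_by_rep), is.matrix(estimates_by_rep),
            nrow(ses_by_rep) >= 2)
  labs <- colnames(estimates_by_rep)
  types <- type_map[labs]
  M_se <- colMeans(ses_by_rep)
  SD <- apply(estimates_by_rep, 2, sd)
  keep <- SD > 0 & !is.na(M_se)
  if (any(SD == 0)) {
    message(sum(SD == 0), " parameter(s) with zero empirical SD excluded ",
            "from SE-bias aggregation")
  }
  rel <- abs(M_se[keep] - SD[keep]) / SD[keep]
  out <- tapply(rel, types[keep], mean)
  setNames(as.numeric(out), names(out))
}

#' Deterministic per-replication seed
#'
#' Replication seeds are derived from the base seed, the condition id, and
#' the replication index by a fixed affine map modulo a Mersenne prime, so
#' partial reruns reproduce individual replications.
#'
#' @param base_seed Integer base seed.
#' @param condition_id Integer condition identifier.
#' @param rep Replication index.
#' @return Integer seed.
#' @export
replication_seed <- function(base_seed, condition_id, rep) {
  m <- 2147483647
  s <- (as.numeric(base_seed) %% m) * 1000003 + condition_id * 10007 + rep * 7919
  as.integer(s %% m + 1)
}

#' Run one Monte-Carlo condition
#'
#' Derives the population parameters for the condition's consistency level,
#' simulates `n_reps` datasets with deterministic per-replication seeds,
#' fits each by two-level maximum likelihood, and aggregates convergence,
#' improper-solution rates, per-type parameter and standard-error bias, and
#' the chi-square values.  Non-converged replications are excluded from the
#' bias statistics but counted in the convergence rate.
#'
#' @param design Measurement design (with `n_targets`/`n_raters` set).
#' @param consistency `"low"` or `"high"` (or an [population_targets()]).
#' @param n_reps Number of replications.
#' @param base_seed Base seed.
#' @param condition_id Integer id entering the per-replication seeds.
#' @param mi Invariance level fitted (and assumed in the population).
#' @param se Compute standard errors per replication (needed for [seb()]).
#' @param chisq Compute chi-square per replication.
#' @param out_dir Optional directory; per-replication results are persisted
#'   as CSV and reused when `resume = TRUE`.
#' @param resume Reuse persisted replications instead of recomputing.
#' @param ... Passed to [fit_ml()].
#' @return An object of class `lscom_mc`.
#' @export
run_condition <- function(design, consistency = "low", n_reps = 100,
                          base_seed = 1, condition_id = 1L, mi = "strong",
                          se = TRUE, chisq = TRUE, out_dir = NULL,
                          resume = FALSE, ...) {
  stopifnot(inherits(design, "lscom_design"))
  targets <- if (inherits(consistency, "lscom_targets")) consistency
             else population_targets(consistency)
  template <- build_template(design, mi = mi)
  nfree <- count_free_parameters(template)
  if (design$n_targets < nfree) {
    stop(sprintf(paste0("condition infeasible: %d targets for %d free ",
                        "parameters"), design$n_targets, nfree),
         call. = FALSE)
  }
  pop <- derive_population_params(targets, design)
  cm <- compile_model(template)
  truth <- natural_from_params(cm, align_params(pop, template))
  labels <- cm$nat$label
  type_map <- setNames(cm$nat$type, labels)

  est <- ses <- matrix(NA_real_, n_reps, length(labels),
                       dimnames = list(NULL, labels))
  converged <- logical(n_reps)
  chi2 <- dfv <- rep(NA_real_, n_reps)
  hw <- matrix(FALSE, n_reps, 4,
               dimnames = list(NULL, c("Phi_B_nonPSD", "Phi_W_nonPSD",
                                       "negative_theta", "correlation_gt_1")))
  seeds <- integer(n_reps)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (n_reps > 0) for (r in seq_len(n_reps)) {
    seeds[r] <- replication_seed(base_seed, condition_id, r)
    repfile <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("rep_%05d.csv", r))
    }
    if (resume && !is.null(repfile) && file.exists(repfile)) {
      stored <- read.csv(repfile)
      est[r, stored$label] <- stored$estimate
      ses[r, stored$label] <- stored$se
      converged[r] <- stored$converged[1]
      chi2[r] <- stored$chi_square[1]; dfv[r] <- stored$df[1]
      hw[r, ] <- as.logical(stored[1, colnames(hw)])
      next
    }
    dat <- simulate_dataset(pop, design, seed = seeds[r])
    fit <- fit_ml(template, data = dat, se = se, chisq = chisq, ...)
    est[r, ] <- fit$estimates$estimate
    ses[r, ] <- fit$estimates$se
    converged[r] <- fit$converged
    chi2[r] <- fit$chi_square; dfv[r] <- fit$df
    hw[r, ] <- unlist(fit$heywood$flags)[colnames(hw)]
    if (!is.null(repfile)) {
      stored <- data.frame(label = labels, estimate = est[r, ],
                           se = ses[r, ], true = unname(truth[labels]),
                           converged = converged[r], chi_square = chi2[r],
                           df = dfv[r])
      for (cn in colnames(hw)) stored[[cn]] <- hw[r, cn]
      write.csv(stored, repfile, row.names = FALSE)
    }
  }
  ok <- which(converged)
  peb_v <- seb_v <- NULL
  if (length(ok) >= 1) {
    peb_v <- suppressMessages(
      peb(est[ok, , drop = FALSE], truth, type_map))
  }
  if (se && length(ok) >= 2) {
    seb_v <- suppressMessages(
      seb(ses[ok, , drop = FALSE], est[ok, , drop = FALSE], type_map))
  }
  structure(list(design = design, consistency = targets$label,
                 mi = mi, n_reps = length(converged),
                 base_seed = base_seed, condition_id = condition_id,
                 seeds = seeds,
                 convergence_rate = if (length(converged)) mean(converged)
                                    else NA_real_,
                 heywood_rates = colMeans(hw[ok, , drop = FALSE]),
                 heywood_any_rate = if (length(ok)) {
                   mean(apply(hw[ok, , drop = FALSE], 1, any))
                 } else NA_real_,
                 peb = peb_v, seb = seb_v,
                 truth = truth, estimates = est, ses = ses,
                 converged = converged, chi_square = chi2, df = dfv,
                 free_parameters = nfree),
            class = "lscom_mc")
}

#' @export
print.lscom_mc <- function(x, ...) {
  cat("LS-COM Monte-Carlo condition result\n")
  cat(sprintf("  replications    : %d (convergence rate %.2f)\n",
              x$n_reps, x$convergence_rate))
  cat(sprintf("  improper rate   : %.3f\n", x$heywood_any_rate))
  if (!is.null(x$peb)) {
    cat(sprintf("  max per-type parameter bias : %.3f (%s)\n",
                max(x$peb), names(x$peb)[which.max(x$peb)]))
  }
  if (!is.null(x$seb)) {
    cat(sprintf("  max per-type SE bias        : %.3f (%s)\n",
                max(x$seb), names(x$seb)[which.max(x$seb)]))
  }
  invisible(x)
}

#' Chi-square calibration curve
#'
#' Compares the empirical distribution of replication chi-square values to
#' the reference central chi-square: for each probability `p` on the grid,
#' the proportion of replications with a chi-square below the theoretical
#' p-quantile.  On a well-calibrated test the curve lies on the diagonal;
#' proportions above the diagonal mean the test is too liberal (simulated
#' values run below the reference distribution).  Batches mixing degrees of
#' freedom are grouped automatically.
#'
#' @param chi_square Vector of chi-square values.
#' @param df Matching degrees of freedom (scalar or vector).
#' @param probs Probability grid.
#' @param alpha Nominal level for the rejection-rate summary.
#' @return A data.frame (`df`, `p`, `observed`) with the empirical rejection
#'   rate at `alpha` per df group in attribute `"rejection"`.
#' @export
chisq_calibration <- function(chi_square, df,
                              probs = seq(0.05, 0.95, by = 0.05),
                              alpha = 0.05) {
  df <- rep_len(df, length(chi_square))
  keep <- is.finite(chi_square) & is.finite(df)
  chi_square <- chi_square[keep]
  df <- df[keep]
  if (length(chi_square) < 50) {
    warning("fewer than 50 chi-square values; the calibration curve will ",
            "be unstable", call. = FALSE)
  }
  idx <- split(seq_along(chi_square), df)
  out <- do.call(rbind, lapply(idx, function(ii) {
    d <- df[ii[1]]
    data.frame(df = d, p = probs,
               observed = vapply(probs, function(p) {
                 mean(chi_square[ii] <= qchisq(p, d))
               }, numeric(1)))
  }))
  rownames(out) <- NULL
  rej <- vapply(idx, function(ii) {
    mean(chi_square[ii] > qchisq(1 - alpha, df[ii[1]]))
  }, numeric(1))
  attr(out, "rejection") <- rej
  attr(out, "alpha") <- alpha
  out
}
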
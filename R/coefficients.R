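#' Consistency, method-specificity and reliability coefficients
#'
#' Computes the variance-component coefficients of the LS-COM model for every
#' indicator, on two scales.  `*_true` coefficients are shares of true
#' (error-free) variance: consistency, common/unique method specificity and
#' the rater-consistency coefficient divide by `Var(Y) - Var(error)`, so the
#' relevant shares sum to one.  `*_observed` coefficients are shares of total
#' observed variance, the scale on which simulation populations are targeted;
#' there, consistency plus method specificity equals reliability.
#'
#' For indicators of the structurally different non-reference methods the
#' true-variance identity is `con + ms = 1`; for interchangeable-set
#' indicators it is `con + cms + ums = 1`, and the rater consistency
#' coefficient (`rc`, the true intraclass correlation of error-free rater
#' scores) equals `con + cms`.  Reference-method indicators measure only the
#' state factor, so their reliability is the state share of total variance
#' and method coefficients are undefined (`NA`).
#'
#' When an indicator has zero true variance the true-scale coefficients are
#' undefined and returned as `NA`.
#'
#' @param params A [parameter_set()].
#' @return A data.frame, one row per indicator, with columns `con_true`,
#'   `ms_true`, `cms_true`, `ums_true`, `rc_true`, `con_l2_true` (consistency
#'   of the expected interchangeable rating), the corresponding `*_observed`
#'   columns, and `rel` (reliability).
#' @export
compute_coefficients <- function(params) {
  stopifnot(inherits(params, "lscom_params"))
  dv <- decompose_variance(params)
  n <- nrow(dv)
  true_var <- dv$total - dv$var_error
  undef <- true_var <= 0
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)

  out <- dv[c("name", "i", "j", "k", "l", "role", "level", "total")]
  is_ref <- dv$role == "reference_structural"
  is_struct <- dv$role == "nonreference_structural"
  is_int <- dv$role == "interchangeable_set"

  out$rel <- 1 - dv$var_error / dv$total

  out$con_true <- safe_div(dv$var_state, true_var)
  out$con_true[is_ref] <- NA_real_
  out$ms_true <- ifelse(is_struct, safe_div(dv$var_M, true_var), NA_real_)
  out$cms_true <- ifelse(is_int, safe_div(dv$var_CM, true_var), NA_real_)
  out$ums_true <- ifelse(is_int, safe_div(dv$var_UM, true_var), NA_real_)
  out$rc_true <- ifelse(is_int, safe_div(dv$var_state + dv$var_CM, true_var),
                        NA_real_)
  ## consistency of the expected (cluster-level) interchangeable rating:
  ## state share of the Level-2 true variance of the rater indicators
  out$con_l2_true <- ifelse(is_int,
                            safe_div(dv$var_state, dv$var_state + dv$var_CM),
                            NA_real_)

  out$con_observed <- ifelse(is_ref, NA_real_, dv$share_state)
  out$ms_observed <- ifelse(is_struct, dv$share_M, NA_real_)
  out$cms_observed <- ifelse(is_int, dv$share_CM, NA_real_)
  out$ums_observed <- ifelse(is_int, dv$share_UM, NA_real_)
  out$rc_observed <- ifelse(is_int, dv$share_state + dv$share_CM, NA_real_)
  out$state_share_observed <- dv$share_state

  out[undef, grep("_true$", names(out))] <- NA_real_
  out
}

#' Write the coefficient table as delimited text
#'
#' @param coefs Result of [compute_coefficients()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coefs, path) {
  write.csv(coefs, path, row.names = FALSE)
  invisible(path)
}

#' Latent state mean-change estimates
#'
#' Extracts the estimated latent state means (with standard errors) from a
#' fitted model.  Under the identification used here the first occasion's
#' mean is fixed to zero, so each estimate is the true mean change of its
#' construct relative to occasion one.  Meaningful only under strong (or
#' strict) measurement invariance, where intercepts and loadings are
#' time-invariant; calling this on a configural or weak fit is an error.
#'
#' @param fit A [fit_ml()] result.
#' @return A data.frame with construct, occasion, estimate and SE.
#' @export
latent_state_means <- function(fit) {
  stopifnot(inherits(fit, "lscom_fit"))
  if (!fit$template$mi %in% c("strong", "strict")) {
    stop("latent mean change requires time-invariant loadings and ",
         "intercepts: refit with mi = \"strong\" or \"strict\" ",
         "(the fitted template has mi = \"", fit$template$mi, "\", under ",
         "which the latent state means are fixed to zero)", call. = FALSE)
  }
  est <- fit$estimates
  rows <- est[est$kind == "latent_mean", , drop = FALSE]
  info <- fit$template$params
  info <- info[match(rows$label, info$label), ]
  data.frame(construct = info$j, occasion = info$l,
             estimate = rows$estimate, se = rows$se,
             row.names = NULL)
}
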
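#' Model-implied two-level moment structure
#'
#' Maps a parameter set to the moment structure the model implies: the mean
#' vector of the between part (between-only observed variables plus the
#' cluster-expected values of the rater-level variables), the between
#' covariance matrix over all variables, and the within covariance matrix
#' over the rater-level variables only.
#'
#' The algebra is the usual factor-analytic one at each level:
#' `Sigma_W = Lambda_W Phi_W Lambda_W' + diag(theta_W)` and
#' `Sigma_B = Lambda_B Phi_B Lambda_B' + diag(theta_B)`, with
#' `mu_B = alpha + Lambda_B E(eta_B)`.  Rater-level rows of `Sigma_B` carry
#' no residual term (their residual lives at Level 1).
#'
#' @param template Optional [build_template()] object; when supplied the
#'   parameter set is checked against its variable inventory.
#' @param params An [parameter_set()] object.
#' @return A list of class `lscom_moments` with `mu_B`, `Sigma_B`,
#'   `Sigma_W`, and the variable name inventories.
#' @export
implied_moments <- function(template = NULL, params) {
  stopifnot(inherits(params, "lscom_params"))
  if (!is.null(template)) {
    stopifnot(inherits(template, "lscom_template"))
    if (!identical(template$vars$name, params$vars$name)) {
      bad <- setdiff(template$vars$name, params$vars$name)
      if (!length(bad)) bad <- setdiff(params$vars$name, template$vars$name)
      stop("parameter set does not match the template's variable inventory; ",
           "first offending variable: ", bad[1], call. = FALSE)
    }
  }
  Sigma_B <- params$Lambda_B %*% params$Phi_B %*% t(params$Lambda_B) +
    diag(params$theta_B, length(params$theta_B))
  Sigma_B <- (Sigma_B + t(Sigma_B)) / 2
  dimnames(Sigma_B) <- list(params$vars$name, params$vars$name)
  if (params$p_w > 0) {
    Sigma_W <- params$Lambda_W %*% params$Phi_W %*% t(params$Lambda_W) +
      diag(params$theta_W, params$p_w)
    Sigma_W <- (Sigma_W + t(Sigma_W)) / 2
    wn <- params$vars$name[params$vars$level == "rater"]
    dimnames(Sigma_W) <- list(wn, wn)
  } else {
    Sigma_W <- matrix(0, 0, 0)
  }
  mu_B <- params$alpha + as.numeric(params$Lambda_B %*% params$factor_means)
  structure(list(mu_B = setNames(mu_B, params$vars$name),
                 Sigma_B = Sigma_B, Sigma_W = Sigma_W,
                 var_names = params$vars$name,
                 rater_vars = params$vars$name[params$vars$level == "rater"]),
            class = "lscom_moments")
}

#' Per-indicator variance decomposition
#'
#' Splits the implied total variance of every indicator into additive
#' sources: latent state, method factor (structurally different methods),
#' common method factor and unique method factor (interchangeable set), and
#' measurement error.  Sources are additive because every indicator's
#' loadings touch mutually uncorrelated factors.
#'
#' @param params A parameter set.
#' @return A data.frame with one row per indicator: absolute variance
#'   contributions (`var_*`), the implied `total`, and shares (`share_*`)
#'   that sum to one.
#' @export
decompose_variance <- function(params) {
  stopifnot(inherits(params, "lscom_params"))
  vars <- params$vars
  fB <- params$factors_B
  out <- vars[c("name", "i", "j", "k", "l", "role", "level")]
  n <- nrow(vars)
  out$var_state <- out$var_M <- out$var_CM <- out$var_UM <- out$var_error <-
    numeric(n)
  wnames <- vars$name[vars$level == "rater"]
  for (v in seq_len(n)) {
    lamB <- params$Lambda_B[v, ]
    contrib <- function(type) {
      idx <- which(fB$type == type)
      if (!length(idx)) return(0)
      as.numeric(lamB[idx] %*% params$Phi_B[idx, idx, drop = FALSE] %*% lamB[idx])
    }
    out$var_state[v] <- contrib("S")
    out$var_M[v] <- contrib("M")
    out$var_CM[v] <- contrib("CM")
    if (vars$level[v] == "rater") {
      w <- match(vars$name[v], wnames)
      lamW <- params$Lambda_W[w, ]
      out$var_UM[v] <- as.numeric(lamW %*% params$Phi_W %*% lamW)
      out$var_error[v] <- params$theta_W[w]
    } else {
      out$var_UM[v] <- 0
      out$var_error[v] <- params$theta_B[v]
    }
  }
  out$total <- out$var_state + out$var_M + out$var_CM + out$var_UM + out$var_error
  for (src in c("state", "M", "CM", "UM", "error")) {
    out[[paste0("share_", src)]] <- out[[paste0("var_", src)]] / out$total
  }
  out
}

#' Export moment matrices as labeled delimited text
#'
#' @param moments An [implied_moments()] result.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_moments <- function(moments, dir) {
  stopifnot(inherits(moments, "lscom_moments"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mu = file.path(dir, "mu_B.csv"),
             Sigma_B = file.path(dir, "Sigma_B.csv"),
             Sigma_W = file.path(dir, "Sigma_W.csv"))
  write.csv(data.frame(variable = names(moments$mu_B), mean = moments$mu_B,
                       row.names = NULL), paths["mu"], row.names = FALSE)
  write.csv(as.data.frame(moments$Sigma_B), paths["Sigma_B"])
  write.csv(as.data.frame(moments$Sigma_W), paths["Sigma_W"])
  invisible(paths)
}
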
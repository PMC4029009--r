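#' Construct a numeric LS-COM parameter set
#'
#' A parameter set holds numeric values for every model quantity: factor
#' loading matrices at both levels, intercepts, latent state means, the
#' latent covariance matrices `Phi_B` (states, method and common method
#' factors, target level) and `Phi_W` (unique method factors, rater level),
#' and residual variances `theta_B` / `theta_W`.  Rater-level indicators
#' have no target-level residual; their `theta_B` entries are structurally
#' zero.
#'
#' @param design The [design_spec()] the values refer to.
#' @param Lambda_B Loading matrix of all observed variables on the Level-2
#'   factors (rows in the canonical variable order, columns in factor order).
#' @param Lambda_W Loading matrix of rater-level variables on the unique
#'   method factors.
#' @param alpha Intercept vector (length `nrow(Lambda_B)`).
#' @param factor_means Means of the Level-2 factors; method-factor entries
#'   must be zero.
#' @param Phi_B,Phi_W Latent covariance matrices (symmetric).
#' @param theta_B,theta_W Residual variance vectors.
#' @return An object of class `lscom_params`.
#' @export
parameter_set <- function(design, Lambda_B, Lambda_W, alpha, factor_means,
                          Phi_B, Phi_W, theta_B, theta_W) {
  sk <- lscom_skeleton(design)
  p <- nrow(sk$vars); qB <- nrow(sk$factors_B); qW <- nrow(sk$factors_W)
  p_w <- sk$p_w
  dim_fail <- function(what, got, want) {
    stop(sprintf("%s has dimension %s, expected %s", what,
                 paste(got, collapse = "x"), paste(want, collapse = "x")),
         call. = FALSE)
  }
  if (!all(dim(Lambda_B) == c(p, qB))) dim_fail("Lambda_B", dim(Lambda_B), c(p, qB))
  if (qW > 0 && !all(dim(Lambda_W) == c(p_w, qW)))
    dim_fail("Lambda_W", dim(Lambda_W), c(p_w, qW))
  if (length(alpha) != p) dim_fail("alpha", length(alpha), p)
  if (length(factor_means) != qB) dim_fail("factor_means", length(factor_means), qB)
  if (!all(dim(Phi_B) == c(qB, qB))) dim_fail("Phi_B", dim(Phi_B), c(qB, qB))
  if (qW > 0 && !all(dim(Phi_W) == c(qW, qW))) dim_fail("Phi_W", dim(Phi_W), c(qW, qW))
  if (length(theta_B) != p) dim_fail("theta_B", length(theta_B), p)
  if (length(theta_W) != p_w) dim_fail("theta_W", length(theta_W), p_w)
  if (max(abs(Phi_B - t(Phi_B))) > 1e-10) stop("Phi_B must be symmetric", call. = FALSE)
  if (qW > 0 && max(abs(Phi_W - t(Phi_W))) > 1e-10)
    stop("Phi_W must be symmetric", call. = FALSE)
  is_state <- sk$factors_B$type == "S"
  if (any(abs(factor_means[!is_state]) > 1e-12))
    stop("method-factor means are structurally zero", call. = FALSE)
  if (any(abs(Phi_B[is_state, !is_state]) > 1e-12))
    stop("state-method covariances are structurally zero in Phi_B", call. = FALSE)
  if (p_w > 0 && any(abs(theta_B[sk$vars$level == "rater"]) > 1e-12))
    stop("rater-level indicators have no Level-2 residual; the corresponding ",
         "theta_B entries must be zero", call. = FALSE)
  dimnames(Lambda_B) <- list(sk$vars$name, sk$factors_B$name)
  if (qW > 0) {
    dimnames(Lambda_W) <- list(sk$vars$name[sk$vars$level == "rater"],
                               sk$factors_W$name)
    dimnames(Phi_W) <- list(sk$factors_W$name, sk$factors_W$name)
  }
  dimnames(Phi_B) <- list(sk$factors_B$name, sk$factors_B$name)
  structure(list(design = design, vars = sk$vars,
                 factors_B = sk$factors_B, factors_W = sk$factors_W,
                 p_b = sk$p_b, p_w = sk$p_w,
                 Lambda_B = Lambda_B, Lambda_W = Lambda_W,
                 alpha = setNames(as.numeric(alpha), sk$vars$name),
                 factor_means = setNames(as.numeric(factor_means),
                                         sk$factors_B$name),
                 Phi_B = Phi_B, Phi_W = Phi_W,
                 theta_B = setNames(as.numeric(theta_B), sk$vars$name),
                 theta_W = setNames(as.numeric(theta_W),
                                    sk$vars$name[sk$vars$level == "rater"])),
            class = "lscom_params")
}

#' @export
print.lscom_params <- function(x, ...) {
  cat("LS-COM parameter set\n")
  cat(sprintf("  observed vars : %d between-only, %d rater-level\n",
              x$p_b, x$p_w))
  cat(sprintf("  L2 factors    : %d;  L1 factors: %d\n",
              nrow(x$factors_B), nrow(x$factors_W)))
  cat(sprintf("  mean state variance %.3f, mean residual variance %.3f\n",
              mean(diag(x$Phi_B)[x$factors_B$type == "S"]),
              mean(c(x$theta_B[x$vars$level == "between"], x$theta_W))))
  invisible(x)
}

#' Rescale a parameter set to a template's identification constraints
#'
#' A population parameter set is usually stated on the unit-variance latent
#' scale, while a fitted template scales each factor by fixing one loading.
#' This transformation rescales every latent factor so that its fixed
#' scaling loading takes the template's fixed value, leaving the implied
#' moment structure unchanged.  The result is the "true value" vector
#' against which estimates from that template are compared.
#'
#' @param params An `lscom_params` object.
#' @param template The template providing the identification constraints.
#' @return A rescaled `lscom_params` object.
#' @export
align_params <- function(params, template) {
  stopifnot(inherits(params, "lscom_params"), inherits(template, "lscom_template"))
  tp <- template$params
  scale_for <- function(factors, Lambda, kinds) {
    a <- rep(1, nrow(factors))
    for (f in seq_len(nrow(factors))) {
      fx <- tp[tp$status == "fixed" & tp$kind %in% kinds &
                 !is.na(tp$col) & tp$col == factors$name[f] &
                 !is.na(tp$value) & tp$value != 0, , drop = FALSE]
      if (nrow(fx)) {
        a[f] <- Lambda[fx$row[1], factors$name[f]] / fx$value[1]
      }
    }
    a
  }
  aB <- scale_for(params$factors_B, params$Lambda_B,
                  c("loading_S", "loading_M", "loading_CM"))
  out <- params
  out$Lambda_B <- sweep(params$Lambda_B, 2, aB, "/")
  out$Phi_B <- diag(aB, nrow(params$factors_B)) %*% params$Phi_B %*%
    diag(aB, nrow(params$factors_B))
  dimnames(out$Phi_B) <- dimnames(params$Phi_B)
  out$factor_means <- params$factor_means * aB
  if (params$p_w > 0) {
    aW <- scale_for(params$factors_W, params$Lambda_W, "loading_UM")
    out$Lambda_W <- sweep(params$Lambda_W, 2, aW, "/")
    out$Phi_W <- diag(aW, nrow(params$factors_W)) %*% params$Phi_W %*%
      diag(aW, nrow(params$factors_W))
    dimnames(out$Phi_W) <- dimnames(params$Phi_W)
  }
  out
}
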
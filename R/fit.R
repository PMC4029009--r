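stats_for_cpp <- function(stats) {
  list(groups = lapply(stats$groups, function(g) {
    list(T = as.numeric(g$T), n = as.numeric(g$n), d = as.numeric(g$d),
         SW = g$SW, SB = g$SB, mean = as.numeric(g$mean))
  }))
}

# method-of-moments style start values: unit loadings, residuals at half the
# sample variances, state variances from between covariances of the two
# reference indicators (error-free cross moments), modest method variances
start_theta <- function(template, cm, stats) {
  vars <- template$vars
  fB <- template$factors_B; fW <- template$factors_W
  bsel <- vars$level == "between"
  p <- nrow(vars)
  var_b <- diag(stats$cov_between)

  Lambda_B <- cm$cpp$LB0
  Lambda_B[cm$cpp$lb_pos + 1L] <- 1
  Lambda_W <- cm$cpp$LW0
  if (length(cm$cpp$lw_pos)) Lambda_W[cm$cpp$lw_pos + 1L] <- 1
  alpha <- as.numeric(stats$grand_mean)
  means <- numeric(nrow(fB))
  theta_B <- ifelse(bsel, pmax(0.5 * var_b, 1e-3), 0)
  theta_W <- pmax(0.5 * stats$var_within, 1e-3)

  phi_diag_B <- numeric(nrow(fB))
  for (f in seq_len(nrow(fB))) {
    j <- fB$j[f]; l <- fB$l[f]
    if (fB$type[f] == "S") {
      v1 <- match(var_label(1, j, 1, l), stats$var_names)
      v2 <- match(var_label(2, j, 1, l), stats$var_names)
      phi_diag_B[f] <- min(max(stats$cov_between[v1, v2], 0.05),
                           2 * max(var_b, 1))
    } else {
      first <- match(var_label(1, j, fB$k[f], l), stats$var_names)
      phi_diag_B[f] <- max(0.3 * stats$cov_between[first, first], 0.05)
    }
  }
  Phi_B <- diag(phi_diag_B, nrow(fB))
  if (nrow(fW)) {
    phi_diag_W <- vapply(seq_len(nrow(fW)), function(f) {
      first <- match(var_label(1, fW$j[f], fW$k[f], fW$l[f]),
                     vars$name[!bsel])
      max(0.5 * stats$var_within[first], 0.05)
    }, numeric(1))
    Phi_W <- diag(phi_diag_W, nrow(fW))
  } else {
    Phi_W <- matrix(0, 0, 0)
  }
  mats <- list(Lambda_B = Lambda_B, Lambda_W = Lambda_W, alpha = alpha,
               factor_means = means, Phi_B = Phi_B, Phi_W = Phi_W,
               theta_B = theta_B, theta_W = theta_W)
  nat <- cm$nat
  n_id <- sum(nat$kind %in% id_kinds)
  n_log <- sum(nat$kind %in% log_kinds)
  natv <- natural_from_matrices(cm, mats)
  theta <- numeric(cm$n_theta)
  theta[seq_len(n_id)] <- natv[seq_len(n_id)]
  theta[n_id + seq_len(n_log)] <- log(pmax(natv[n_id + seq_len(n_log)], 1e-6))
  for (blk in c(cm$cpp$blocks_B, cm$cpp$blocks_W)) {
    m <- length(blk$idx)
    k <- 1L
    for (cc in seq_len(m)) {
      for (rr in cc:m) {
        ## start at zero latent correlations: log-Cholesky diagonal carries
        ## half the log variance, off-diagonals are zero
        theta[blk$th[k] + 1L] <- if (rr == cc) {
          0.5 * log(max(natv[blk$th[k] + 1L], 1e-4))
        } else 0
        k <- k + 1L
      }
    }
  }
  theta
}

#' Fit an LS-COM model by two-level maximum likelihood
#'
#' Full-information Gaussian maximum likelihood over the unconstrained
#' reparameterization (log residual variances, block log-Cholesky latent
#' covariances); equality-constrained parameters are estimated as single
#' parameters.  Standard errors come from the inverse of the numerically
#' differentiated observed information, mapped to the natural scale by the
#' delta method.  Non-convergence returns a result flagged
#' `converged = FALSE` (never an error); having fewer targets than free
#' parameters triggers a warning but the fit is attempted.
#'
#' @param template Model template.
#' @param data Two-level dataset (ignored when `stats` is given).
#' @param stats Optional precomputed [compute_sufficient_stats()].
#' @param start Optional `lscom_params` start values (on the identified
#'   scale); default uses the method-of-moments heuristic.
#' @param se Compute standard errors (the expensive Hessian step).
#' @param chisq Compute the saturated model and the chi-square statistic.
#' @param max_iter Iteration cap (default 1000).
#' @param gtol Relative-gradient convergence tolerance.
#' @param n_starts Number of additional jittered starts tried on
#'   non-convergence.
#' @return An object of class `lscom_fit`.
#' @export
fit_ml <- function(template, data = NULL, stats = NULL, start = NULL,
                   se = TRUE, chisq = TRUE, max_iter = 1000, gtol = 1e-6,
                   n_starts = 3) {
  stopifnot(inherits(template, "lscom_template"))
  if (is.null(stats)) stats <- compute_sufficient_stats(data, template)
  nfree <- count_free_parameters(template)
  if (stats$n_targets < nfree) {
    warning(sprintf(paste0(
      "fewer targets (%d) than free parameters (%d); the model is ",
      "underidentified but the fit is attempted"),
      stats$n_targets, nfree), call. = FALSE)
  }
  cm <- compile_model(template)
  cstats <- stats_for_cpp(stats)
  obj <- function(th) cpp_neg2ll(th, cm$cpp, cstats)
  gr <- function(th) cpp_neg2ll_grad(th, cm$cpp, cstats)

  theta0 <- if (is.null(start)) start_theta(template, cm, stats)
            else params_to_theta(cm, start)
  run <- function(th0) {
    ## already stationary (e.g. restarted from a solution): nothing to do
    f0 <- obj(th0)
    g0 <- gr(th0)
    relgrad0 <- max(abs(g0) * pmax(abs(th0), 1)) / max(abs(f0), 1)
    if (is.finite(f0) && f0 < BIG_OBJECTIVE && relgrad0 < max(gtol, 1e-4)) {
      return(list(par = th0, objective = f0, converged = TRUE,
                  iterations = 0L, relgrad = relgrad0, convergence = 0L))
    }
    res <- nlminb(th0, obj, gradient = gr,
                  control = list(iter.max = max_iter,
                                 eval.max = 4L * max_iter,
                                 rel.tol = 1e-12))
    g <- gr(res$par)
    relgrad <- max(abs(g) * pmax(abs(res$par), 1)) / max(abs(res$objective), 1)
    ## converged: the scaled gradient criterion is met outright, or the
    ## optimizer reports success with the gradient at least near-stationary
    res$converged <- res$objective < BIG_OBJECTIVE &&
      (relgrad < gtol || (res$convergence == 0 && relgrad < 1e-2))
    res$relgrad <- relgrad
    res
  }
  best <- run(theta0)
  tries <- 0L
  while (!best$converged && tries < n_starts) {
    tries <- tries + 1L
    cand <- run(theta0 + rnorm(length(theta0), sd = 0.2))
    if ((cand$converged && !best$converged) ||
        (cand$converged == best$converged && cand$objective < best$objective)) {
      best <- cand
    }
  }
  theta <- best$par
  logL <- -0.5 * best$objective

  nat <- natural_from_theta(cm, theta)
  se_nat <- rep(NA_real_, length(nat))
  vcov_nat <- NULL
  if (se && best$converged) {
    H <- cpp_neg2ll_hess(theta, cm$cpp, cstats)
    info <- H / 2
    vth <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vth)) {
      J <- jacobian_natural(cm, theta)
      vcov_nat <- J %*% vth %*% t(J)
      dv <- diag(vcov_nat)
      se_nat <- ifelse(dv > 0, sqrt(pmax(dv, 0)), NA_real_)
      dimnames(vcov_nat) <- list(cm$nat$label, cm$nat$label)
    }
  }

  sat <- NULL; chi2 <- df <- pval <- NA_real_
  if (chisq) {
    sat <- fit_saturated(stats)
    chi2 <- max(0, 2 * (sat$logL - logL))
    df <- sat$moment_count - nfree
    pval <- pchisq(chi2, df, lower.tail = FALSE)
  }
  params_hat <- theta_to_params(cm, theta)
  estimates <- data.frame(label = cm$nat$label, kind = cm$nat$kind,
                          type = cm$nat$type, estimate = unname(nat),
                          se = unname(se_nat), stringsAsFactors = FALSE)
  structure(list(template = template, cm = cm, theta = theta,
                 estimates = estimates, vcov = vcov_nat,
                 params = params_hat,
                 logL = logL,
                 logL_saturated = if (chisq) sat$logL else NA_real_,
                 chi_square = chi2, df = df, p_value = pval,
                 converged = best$converged, iterations = best$iterations,
                 relgrad = best$relgrad,
                 heywood = detect_heywood(params_hat, boundary = 1e-3),
                 n_targets = stats$n_targets,
                 cluster_sizes = stats$cluster_sizes,
                 n_free = nfree),
            class = "lscom_fit")
}

BIG_OBJECTIVE <- 1e11

#' @export
print.lscom_fit <- function(x, ...) {
  cat("LS-COM two-level ML fit\n")
  cat(sprintf("  free parameters : %d\n", x$n_free))
  cat(sprintf("  targets         : %d (raters per target: %s)\n",
              x$n_targets,
              paste(range(x$cluster_sizes), collapse = "-")))
  cat(sprintf("  logL            : %.3f\n", x$logL))
  if (!is.na(x$chi_square)) {
    cat(sprintf("  chi-square      : %.3f on %d df (p = %.4f)\n",
                x$chi_square, x$df, x$p_value))
  }
  cat(sprintf("  converged       : %s (%d iterations)\n",
              x$converged, x$iterations))
  if (any(unlist(x$heywood$flags))) {
    cat("  improper-solution flags:",
        paste(names(which(unlist(x$heywood$flags))), collapse = ", "), "\n")
  }
  invisible(x)
}

# numerical Jacobian of the natural parameters with respect to theta
jacobian_natural <- function(cm, theta, h = 1e-6) {
  n <- length(theta)
  f0 <- natural_from_theta(cm, theta)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    hi <- h * (1 + abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + hi
    tm <- theta; tm[i] <- tm[i] - hi
    J[, i] <- (natural_from_theta(cm, tp) - natural_from_theta(cm, tm)) / (2 * hi)
  }
  J
}

#' Detect improper (Heywood) solutions
#'
#' Checks a parameter set (or the final iterate of a fit) for inadmissible
#' or boundary values: a non-positive-definite latent covariance matrix at
#' either level, negative residual variances, or latent correlations at or
#' beyond one in absolute value.  With `boundary = 0` only literal
#' violations are flagged.  A positive `boundary` additionally flags
#' solutions within that margin of the inadmissible region (correlations
#' above `1 - boundary`, smallest relative eigenvalue below `boundary`),
#' which is how fitted models are screened: the unconstrained
#' parameterization used in estimation only reaches the boundary in the
#' limit.
#'
#' @param x A parameter set or fit.
#' @param tol Numerical tolerance for literal violations.
#' @param boundary Boundary margin (see above).
#' @param ... Unused.
#' @return List with `flags` (`Phi_B_nonPSD`, `Phi_W_nonPSD`,
#'   `negative_theta`, `correlation_gt_1`), `any`, and diagnostic details.
#' @export
detect_heywood <- function(x, ...) UseMethod("detect_heywood")

#' @rdname detect_heywood
#' @export
detect_heywood.lscom_params <- function(x, tol = 1e-8, boundary = 0, ...) {
  check_phi <- function(Phi) {
    if (!length(Phi)) return(list(nonpsd = FALSE, maxcorr = 0, eigmin = Inf))
    scale <- mean(diag(Phi))
    eigmin <- min(eigen(Phi, symmetric = TRUE, only.values = TRUE)$values)
    nonpsd <- eigmin < -tol * max(scale, 1) ||
      (boundary > 0 && eigmin < boundary * scale)
    C <- suppressWarnings(stats::cov2cor(Phi))
    off <- abs(C[upper.tri(C)])
    maxcorr <- if (length(off)) max(off, na.rm = TRUE) else 0
    list(nonpsd = nonpsd, maxcorr = maxcorr, eigmin = eigmin)
  }
  bB <- check_phi(x$Phi_B)
  bW <- check_phi(x$Phi_W)
  corr_limit <- if (boundary > 0) 1 - boundary else 1 + tol
  thetas <- c(x$theta_B[x$vars$level == "between"], x$theta_W)
  flags <- list(
    Phi_B_nonPSD = bB$nonpsd,
    Phi_W_nonPSD = bW$nonpsd,
    negative_theta = any(thetas < -tol),
    correlation_gt_1 = max(bB$maxcorr, bW$maxcorr) > corr_limit)
  list(flags = flags, any = any(unlist(flags)),
       details = list(eigmin_Phi_B = bB$eigmin, eigmin_Phi_W = bW$eigmin,
                      max_abs_corr = max(bB$maxcorr, bW$maxcorr),
                      min_theta = min(thetas)))
}

#' @rdname detect_heywood
#' @export
detect_heywood.lscom_fit <- function(x, tol = 1e-8, boundary = 1e-3, ...) {
  detect_heywood(x$params, tol = tol, boundary = boundary)
}

#' Sequential measurement-invariance comparison
#'
#' Fits the model under increasingly restrictive invariance levels
#' (configural, weak, strong, strict) and reports the overall chi-square
#' difference test between successive levels.
#'
#' @param design Measurement design.
#' @param data Two-level dataset.
#' @param policy Correlation policy.
#' @param levels Invariance levels to fit, in nesting order.
#' @param ... Passed to [fit_ml()].
#' @return A data.frame with log-likelihoods, free-parameter counts,
#'   chi-square and difference tests.
#' @export
compare_mi <- function(design, data, policy = correlation_policy(),
                       levels = c("configural", "weak", "strong", "strict"),
                       ...) {
  fits <- lapply(levels, function(mi) {
    fit_ml(build_template(design, mi = mi, policy = policy), data = data,
           se = FALSE, ...)
  })
  out <- data.frame(
    mi = levels,
    n_free = vapply(fits, `[[`, numeric(1), "n_free"),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    chi_square = vapply(fits, `[[`, numeric(1), "chi_square"),
    df = vapply(fits, `[[`, numeric(1), "df"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  out$delta_chi_square <- c(NA, diff(out$chi_square))
  out$delta_df <- c(NA, diff(out$df))
  out$delta_p <- ifelse(is.na(out$delta_chi_square), NA,
                        pchisq(out$delta_chi_square, pmax(out$delta_df, 1),
                               lower.tail = FALSE))
  attr(out, "fits") <- fits
  out
}
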
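#' Two-level sufficient statistics
#'
#' Reduces a two-level dataset to the sufficient statistics of the Gaussian
#' two-level likelihood, grouped by cluster size: per group, the number of
#' targets, the pooled within scatter of the rater-level variables (rater
#' deviations from their cluster means), and the scatter and mean of the
#' per-target between vectors (between-only observations stacked with rater
#' cluster means).
#'
#' @param data An [simulate_dataset()] result or a list with `target_table`
#'   and `rater_table` in the canonical column layout.
#' @param template The model template providing the variable inventory.
#' @return An object of class `lscom_stats`.
#' @export
compute_sufficient_stats <- function(data, template) {
  stopifnot(inherits(template, "lscom_template"))
  vars <- template$vars
  bnames <- vars$name[vars$level == "between"]
  wnames <- vars$name[vars$level == "rater"]
  tt <- data$target_table
  miss <- setdiff(c("target_id", bnames), names(tt))
  if (length(miss)) {
    stop("target table is missing column ", miss[1], call. = FALSE)
  }
  x <- as.matrix(tt[bnames])
  tid_levels <- tt$target_id
  Tn <- nrow(tt)
  p_w <- length(wnames)

  if (p_w > 0) {
    rt <- data$rater_table
    miss <- setdiff(c("target_id", wnames), names(rt))
    if (length(miss)) {
      stop("rater table is missing column ", miss[1], call. = FALSE)
    }
    tid <- factor(rt$target_id, levels = tid_levels)
    if (anyNA(tid)) {
      stop("rater table contains target ids absent from the target table",
           call. = FALSE)
    }
    nr <- as.integer(table(tid))
    if (any(nr < 1)) {
      stop("every target needs at least one rater observation when ",
           "interchangeable-method variables are in the model", call. = FALSE)
    }
    y <- as.matrix(rt[wnames])
    ybar <- rowsum(y, tid) / nr
    dev <- y - ybar[as.integer(tid), , drop = FALSE]
    v <- cbind(x, ybar)
  } else {
    nr <- rep(0L, Tn)
    dev <- matrix(0, 0, 0)
    v <- x
  }
  colnames(v) <- c(bnames, wnames)
  p <- ncol(v)

  groups <- lapply(sort(unique(nr)), function(n) {
    sel <- nr == n
    vg <- v[sel, , drop = FALSE]
    mg <- colMeans(vg)
    SB <- crossprod(sweep(vg, 2, mg))
    if (p_w > 0 && n > 1) {
      rows <- as.integer(tid) %in% which(sel)
      SW <- crossprod(dev[rows, , drop = FALSE])
    } else {
      SW <- matrix(0, p_w, p_w)
    }
    list(T = sum(sel), n = n, d = sum(sel) * max(n - 1, 0),
         SW = SW, SB = SB, mean = mg)
  })

  grand <- colMeans(v)
  SB_pool <- Reduce(`+`, lapply(groups, function(g) {
    g$SB + g$T * tcrossprod(g$mean - grand)
  }))
  cov_between <- SB_pool / max(Tn - 1, 1)
  d_tot <- sum(vapply(groups, `[[`, numeric(1), "d"))
  var_within <- if (p_w > 0 && d_tot > 0) {
    diag(Reduce(`+`, lapply(groups, `[[`, "SW"))) / d_tot
  } else numeric(p_w)

  structure(list(groups = groups, p = p, p_b = length(bnames), p_w = p_w,
                 n_targets = Tn, n_raters_total = sum(nr),
                 cluster_sizes = nr,
                 var_names = c(bnames, wnames),
                 grand_mean = grand, cov_between = cov_between,
                 var_within = var_within),
            class = "lscom_stats")
}

# group-wise -2 log-likelihood given implied moments (R reference path;
# the optimizer uses the equivalent compiled path)
neg2ll_from_moments <- function(mom, stats) {
  p <- stats$p; p_b <- stats$p_b; p_w <- stats$p_w
  SigW <- mom$Sigma_W
  ldW <- 0; SigWinv <- NULL
  if (p_w > 0) {
    ch <- tryCatch(chol(SigW), error = function(e) NULL)
    if (is.null(ch)) return(structure(Inf, singular = TRUE))
    ldW <- 2 * sum(log(diag(ch)))
    SigWinv <- chol2inv(ch)
  }
  out <- 0
  for (g in stats$groups) {
    if (p_w > 0 && g$d > 0) {
      out <- out + g$d * (p_w * log(2 * pi) + ldW) + sum(SigWinv * g$SW)
    }
    ## Jacobian of the (raters) -> (cluster mean, deviations) map
    if (p_w > 0 && g$n > 0) out <- out + g$T * p_w * log(g$n)
    V <- mom$Sigma_B
    if (p_w > 0 && g$n > 0) {
      wi <- (p_b + 1):p
      V[wi, wi] <- V[wi, wi] + SigW / g$n
    }
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(structure(Inf, singular = TRUE))
    Vinv <- chol2inv(ch)
    r <- g$mean - mom$mu_B
    out <- out + g$T * (p * log(2 * pi) + 2 * sum(log(diag(ch)))) +
      sum(Vinv * g$SB) + g$T * sum(r * (Vinv %*% r))
  }
  out
}

#' Two-level log-likelihood of a parameter set
#'
#' Evaluates the Gaussian two-level log-likelihood of `params` given the
#' sufficient statistics: each target's between vector (between-only
#' observations and rater means) contributes through
#' `Sigma_B + Sigma_W / n_t` and the pooled rater deviations through
#' `Sigma_W`.  A singular implied covariance yields `-Inf` with attribute
#' `singular = TRUE` rather than an error, so optimizers can retreat.
#'
#' @param template Model template.
#' @param params Parameter set.
#' @param stats [compute_sufficient_stats()] result.
#' @return The log-likelihood value.
#' @export
loglikelihood <- function(template, params, stats) {
  stopifnot(inherits(stats, "lscom_stats"))
  mom <- implied_moments(template, params)
  if (!identical(stats$var_names, mom$var_names)) {
    stop("statistics and parameter set refer to different variable ",
         "inventories", call. = FALSE)
  }
  n2 <- neg2ll_from_moments(mom, stats)
  if (!is.finite(n2)) return(structure(-Inf, singular = TRUE))
  -0.5 * n2
}

saturated_moment_count <- function(stats) {
  p <- stats$p; p_w <- stats$p_w
  as.integer(p + p * (p + 1) / 2 + p_w * (p_w + 1) / 2)
}

#' Fit the saturated (unrestricted) two-level model
#'
#' Maximizes the same two-level likelihood over an unrestricted mean vector,
#' between covariance matrix, and within covariance matrix.  With balanced
#' cluster sizes the maximum has a closed form (pooled within scatter over
#' its degrees of freedom; between scatter of the target vectors over the
#' number of targets); with unbalanced clusters the likelihood is maximized
#' numerically over a log-Cholesky parameterization.
#'
#' @param stats [compute_sufficient_stats()] result (or a dataset plus
#'   `template` from which statistics are computed).
#' @param template Template used to compute statistics when `stats` is a
#'   dataset.
#' @return List with `logL`, `moment_count`, the fitted `mu`, `Sigma_B`,
#'   `Sigma_W`, and the `method` used.
#' @export
fit_saturated <- function(stats, template = NULL) {
  if (!inherits(stats, "lscom_stats")) {
    stats <- compute_sufficient_stats(stats, template)
  }
  p <- stats$p; p_w <- stats$p_w; p_b <- stats$p_b
  balanced <- length(stats$groups) == 1
  if (balanced) {
    g <- stats$groups[[1]]
    V <- g$SB / g$T
    SigW <- if (p_w > 0 && g$d > 0) g$SW / g$d else matrix(0, p_w, p_w)
    ok <- !inherits(tryCatch(chol(V), error = identity), "error") &&
      (p_w == 0 || g$d == 0 ||
         !inherits(tryCatch(chol(SigW), error = identity), "error"))
    if (ok) {
      SigB <- V
      if (p_w > 0 && g$n > 0) {
        wi <- (p_b + 1):p
        SigB[wi, wi] <- SigB[wi, wi] - SigW / g$n
      }
      ## SigB = V - SigW/n may be slightly indefinite in finite samples; the
      ## likelihood involves it only through V, so the closed form remains
      ## the unrestricted maximum
      jac <- if (p_w > 0 && g$n > 0) g$T * p_w * log(g$n) else 0
      logL <- -0.5 * (g$d * (p_w * log(2 * pi) +
                               if (p_w > 0 && g$d > 0)
                                 2 * sum(log(diag(chol(SigW)))) else 0) +
                        g$d * p_w +
                        g$T * (p * log(2 * pi) + 2 * sum(log(diag(chol(V))))) +
                        g$T * p + jac)
      return(list(logL = logL, moment_count = saturated_moment_count(stats),
                  mu = g$mean, Sigma_B = SigB, Sigma_W = SigW,
                  method = "closed_form", converged = TRUE))
    }
  }
  saturated_numeric(stats)
}

# log-Cholesky parameterized numeric maximization for unbalanced designs
saturated_numeric <- function(stats) {
  p <- stats$p; p_w <- stats$p_w; p_b <- stats$p_b
  nW <- p_w * (p_w + 1) / 2
  nB <- p * (p + 1) / 2
  lower_tri_fill <- function(par, d) {
    L <- matrix(0, d, d)
    L[lower.tri(L, diag = TRUE)] <- par   # column-major lower-tri order
    diag(L) <- exp(diag(L))
    L
  }
  chol_par <- function(S) {
    d <- nrow(S)
    if (!d) return(numeric(0))
    ev <- eigen(S, symmetric = TRUE)
    S <- ev$vectors %*% diag(pmax(ev$values, 1e-6), d) %*% t(ev$vectors)
    L <- t(chol(S))
    out <- numeric(d * (d + 1) / 2)
    pos <- 1L
    for (cc in seq_len(d)) {
      for (rr in cc:d) {
        out[pos] <- if (rr == cc) log(L[rr, cc]) else L[rr, cc]
        pos <- pos + 1L
      }
    }
    out
  }
  obj <- function(par) {
    mu <- par[seq_len(p)]
    LB <- lower_tri_fill(par[p + seq_len(nB)], p)
    SigB <- LB %*% t(LB)
    SigW <- if (p_w > 0) {
      LW <- lower_tri_fill(par[p + nB + seq_len(nW)], p_w)
      LW %*% t(LW)
    } else matrix(0, 0, 0)
    mom <- list(mu_B = mu, Sigma_B = SigB, Sigma_W = SigW)
    v <- neg2ll_from_moments(mom, stats)
    if (!is.finite(v)) 1e12 else v
  }
  nbar <- mean(stats$cluster_sizes)
  SigW0 <- diag(pmax(stats$var_within, 1e-4), p_w)
  SigB0 <- stats$cov_between
  if (p_w > 0) {
    wi <- (p_b + 1):p
    SigB0[wi, wi] <- SigB0[wi, wi] - SigW0 / max(nbar, 1)
  }
  par0 <- c(stats$grand_mean, chol_par(SigB0), chol_par(SigW0))
  res <- nlminb(par0, obj, control = list(iter.max = 2000, eval.max = 8000))
  mu <- res$par[seq_len(p)]
  LB <- lower_tri_fill(res$par[p + seq_len(nB)], p)
  SigB <- LB %*% t(LB)
  SigW <- if (p_w > 0) {
    LW <- lower_tri_fill(res$par[p + nB + seq_len(nW)], p_w)
    LW %*% t(LW)
  } else matrix(0, 0, 0)
  list(logL = -0.5 * res$objective,
       moment_count = saturated_moment_count(stats),
       mu = mu, Sigma_B = SigB, Sigma_W = SigW,
       method = "numeric", converged = res$convergence == 0)
}
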
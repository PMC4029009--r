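#' Target variance shares for a simulation population
#'
#' The two canonical consistency conditions used in the Monte-Carlo study,
#' stated as shares of total observed indicator variance: low consistency
#' (consistency .30, unique and common method specificity .25, structural
#' method specificity .50) and high consistency (.60, .10, .10, .20), both
#' with reliability .80 and a per-indicator jitter of .025 on the
#' consistency share.
#'
#' @param consistency `"low"`, `"high"`, or `"custom"` (then supply shares).
#' @param consistency_share,unique_ms,common_ms,struct_ms,reliability Custom
#'   shares; ignored unless `consistency = "custom"`.
#' @param jitter Per-indicator offset magnitude applied to the consistency
#'   share (error share compensates), spreading indicator reliabilities over
#'   `reliability - jitter` to `reliability + jitter`.
#' @return An object of class `lscom_targets`.
#' @export
population_targets <- function(consistency = c("low", "high", "custom"),
                               consistency_share = NULL, unique_ms = NULL,
                               common_ms = NULL, struct_ms = NULL,
                               reliability = NULL, jitter = 0.025) {
  consistency <- match.arg(consistency)
  vals <- switch(consistency,
    low  = list(consistency = 0.30, unique_ms = 0.25, common_ms = 0.25,
                struct_ms = 0.50, reliability = 0.80),
    high = list(consistency = 0.60, unique_ms = 0.10, common_ms = 0.10,
                struct_ms = 0.20, reliability = 0.80),
    custom = list(consistency = consistency_share, unique_ms = unique_ms,
                  common_ms = common_ms, struct_ms = struct_ms,
                  reliability = reliability))
  if (any(vapply(vals, is.null, logical(1)))) {
    stop("custom targets need consistency_share, unique_ms, common_ms, ",
         "struct_ms and reliability", call. = FALSE)
  }
  err <- 1 - vals$reliability
  if (abs(vals$consistency + vals$unique_ms + vals$common_ms + err - 1) > 1e-10) {
    stop("interchangeable shares must satisfy consistency + unique_ms + ",
         "common_ms + (1 - reliability) = 1", call. = FALSE)
  }
  if (abs(vals$consistency + vals$struct_ms + err - 1) > 1e-10) {
    stop("structural shares must satisfy consistency + struct_ms + ",
         "(1 - reliability) = 1", call. = FALSE)
  }
  shares <- unlist(vals)
  if (any(shares <= 0) || any(shares >= 1)) {
    stop("all shares must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(c(vals, list(jitter = jitter, label = consistency)),
            class = "lscom_targets")
}

#' Default latent correlation structure for simulation populations
#'
#' States correlate .5 across occasions of the same construct and .3 for any
#' cross-construct pair; method factors of the same kind, construct, and
#' method correlate .3 across occasions; every other permitted method-factor
#' pair correlates .2.  State-method, cross-level, and error covariances are
#' structurally zero.
#'
#' @param state_same_construct,state_cross_construct,method_same,method_cross
#'   Correlation values.
#' @return A list of correlation values.
#' @export
latent_correlations <- function(state_same_construct = 0.5,
                                state_cross_construct = 0.3,
                                method_same = 0.3,
                                method_cross = 0.2) {
  list(state_same_construct = state_same_construct,
       state_cross_construct = state_cross_construct,
       method_same = method_same, method_cross = method_cross)
}

#' Derive population parameters from target variance shares
#'
#' Builds a population parameter set whose implied per-indicator variance
#' decomposition reproduces the target shares exactly on average: all latent
#' variances and all total observed variances are one, loadings are square
#' roots of the assigned shares, and residual variances absorb the
#' unreliability.  Per-indicator jitter offsets (equally spaced over
#' `-jitter .. +jitter`, mean exactly zero) are applied to the consistency
#' share, with the error share compensating, so the across-indicator mean of
#' every share equals its target and indicator reliabilities span the
#' targeted range.
#'
#' @param targets A [population_targets()] object.
#' @param design The measurement design.
#' @param rho Latent correlations, see [latent_correlations()].
#' @param intercept Population intercept given every indicator.
#' @param mean_change Population latent state mean at occasions beyond the
#'   first (occasion one has mean zero).
#' @return An [parameter_set()] object.
#' @export
derive_population_params <- function(targets, design,
                                     rho = latent_correlations(),
                                     intercept = 0.5, mean_change = 0.5) {
  stopifnot(inherits(targets, "lscom_targets"), inherits(design, "lscom_design"))
  sk <- lscom_skeleton(design)
  I <- design$n_indicators
  off <- seq(-targets$jitter, targets$jitter, length.out = I)
  off <- off - mean(off)   # exact mean preservation
  err0 <- 1 - targets$reliability

  vars <- sk$vars
  p <- nrow(vars); qB <- nrow(sk$factors_B); qW <- nrow(sk$factors_W)
  Lambda_B <- matrix(0, p, qB, dimnames = list(vars$name, sk$factors_B$name))
  theta_B <- numeric(p)
  wsel <- vars$level == "rater"
  Lambda_W <- matrix(0, sum(wsel), max(qW, 0),
                     dimnames = if (qW) list(vars$name[wsel], sk$factors_W$name))
  theta_W <- numeric(sum(wsel))
  for (v in seq_len(p)) {
    i <- vars$i[v]; j <- vars$j[v]; k <- vars$k[v]; l <- vars$l[v]
    sname <- factor_label("S", j, 1L, l)
    role <- vars$role[v]
    if (role == "reference_structural") {
      st <- targets$reliability + off[i]
      e <- 1 - st
    } else {
      st <- targets$consistency + off[i]
      e <- err0 - off[i]
    }
    if (st <= 0 || st >= 1 || e <= 0) {
      stop("jittered shares leave no room for a valid decomposition of ",
           vars$name[v], call. = FALSE)
    }
    Lambda_B[v, sname] <- sqrt(st)
    if (role == "nonreference_structural") {
      Lambda_B[v, factor_label("M", j, k, l)] <- sqrt(targets$struct_ms)
      theta_B[v] <- e
    } else if (role == "interchangeable_set") {
      Lambda_B[v, factor_label("CM", j, k, l)] <- sqrt(targets$common_ms)
      w <- match(vars$name[v], vars$name[wsel])
      Lambda_W[w, factor_label("UM", j, k, l)] <- sqrt(targets$unique_ms)
      theta_W[w] <- e
    } else {
      theta_B[v] <- e
    }
  }

  corr_B <- diag(qB)
  fB <- sk$factors_B
  for (a in seq_len(qB)) for (b in seq_len(qB)) {
    if (a == b) next
    ta <- fB$type[a]; tb <- fB$type[b]
    if (ta == "S" && tb == "S") {
      corr_B[a, b] <- if (fB$j[a] == fB$j[b]) rho$state_same_construct
                      else rho$state_cross_construct
    } else if (ta != "S" && tb != "S") {
      same <- ta == tb && fB$j[a] == fB$j[b] && fB$k[a] == fB$k[b]
      corr_B[a, b] <- if (same) rho$method_same else rho$method_cross
    }   # state-method stays zero
  }
  corr_W <- diag(max(qW, 1))
  if (qW > 1) {
    fW <- sk$factors_W
    for (a in seq_len(qW)) for (b in seq_len(qW)) {
      if (a != b) {
        corr_W[a, b] <- if (fW$j[a] == fW$j[b]) rho$method_same
                        else rho$method_cross
      }
    }
  }
  for (nm in list(list(corr_B, "Phi_B"), list(corr_W, "Phi_W"))) {
    ev <- min(eigen(nm[[1]], symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10) {
      stop("latent correlation structure does not yield a positive definite ",
           nm[[2]], call. = FALSE)
    }
  }
  means <- ifelse(fB$type == "S" & fB$l > 1L, mean_change, 0)
  parameter_set(design,
                Lambda_B = Lambda_B, Lambda_W = Lambda_W,
                alpha = rep(intercept, p), factor_means = means,
                Phi_B = corr_B, Phi_W = corr_W[seq_len(max(qW, 0)),
                                               seq_len(max(qW, 0)), drop = FALSE],
                theta_B = theta_B, theta_W = theta_W)
}

#' Simulate a two-level MTMM dataset
#'
#' Draws target-level latent factors from `N(means, Phi_B)`, rater-level
#' unique method factors from `N(0, Phi_W)` independently for each rater,
#' independent Gaussian measurement errors at each level, and assembles the
#' observed variables through the measurement equations.  Fully reproducible
#' from the seed.
#'
#' @param params Population [parameter_set()].
#' @param design Measurement design (defaults to the one in `params`);
#'   supplies `n_targets` and `n_raters`.
#' @param seed Integer seed (required).
#' @return An object of class `lscom_dataset`: `target_table` (one row per
#'   target, between-only indicators), `rater_table` (one row per
#'   rater-within-target, interchangeable indicators), and provenance.
#' @export
simulate_dataset <- function(params, design = params$design, seed) {
  stopifnot(inherits(params, "lscom_params"))
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  for (M in list(params$Phi_B, params$Phi_W)) {
    if (length(M) && min(eigen(M, symmetric = TRUE,
                               only.values = TRUE)$values) < -1e-10) {
      stop("latent covariance matrix is not positive semi-definite",
           call. = FALSE)
    }
  }
  set.seed(seed)
  Tn <- design$n_targets
  nr <- design$n_raters
  has_w <- params$p_w > 0
  if (has_w && length(nr) == 1) nr <- rep(nr, Tn)
  vars <- params$vars
  bsel <- vars$level == "between"; wsel <- !bsel
  qB <- nrow(params$factors_B)

  cB <- chol(params$Phi_B + diag(1e-12, qB))
  etaB <- matrix(rnorm(Tn * qB), Tn, qB) %*% cB
  etaB <- sweep(etaB, 2, params$factor_means, "+")

  Yb <- sweep(etaB %*% t(params$Lambda_B[bsel, , drop = FALSE]), 2,
              params$alpha[bsel], "+")
  if (any(bsel)) {
    Yb <- Yb + matrix(rnorm(Tn * sum(bsel)), Tn) %*%
      diag(sqrt(params$theta_B[bsel]), sum(bsel))
  }
  target_table <- data.frame(target_id = seq_len(Tn))
  target_table[vars$name[bsel]] <- as.data.frame(Yb)

  rater_table <- data.frame(target_id = integer(), rater_id = integer())
  if (has_w) {
    R <- sum(nr)
    tid <- rep(seq_len(Tn), nr)
    qW <- nrow(params$factors_W)
    cW <- chol(params$Phi_W + diag(1e-12, qW))
    um <- matrix(rnorm(R * qW), R, qW) %*% cW
    Yw <- sweep(etaB[tid, , drop = FALSE] %*%
                  t(params$Lambda_B[wsel, , drop = FALSE]), 2,
                params$alpha[wsel], "+") +
      um %*% t(params$Lambda_W) +
      matrix(rnorm(R * sum(wsel)), R) %*%
        diag(sqrt(params$theta_W), sum(wsel))
    rater_table <- data.frame(target_id = tid,
                              rater_id = sequence(nr))
    rater_table[vars$name[wsel]] <- as.data.frame(Yw)
  }
  structure(list(target_table = target_table, rater_table = rater_table,
                 design = design, seed = as.integer(seed),
                 params = params),
            class = "lscom_dataset")
}

#' @export
print.lscom_dataset <- function(x, ...) {
  cat("LS-COM two-level dataset\n")
  cat(sprintf("  targets : %d rows x %d columns\n",
              nrow(x$target_table), ncol(x$target_table)))
  cat(sprintf("  raters  : %d rows x %d columns\n",
              nrow(x$rater_table), ncol(x$rater_table)))
  cat(sprintf("  seed    : %d\n", x$seed))
  invisible(x)
}
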
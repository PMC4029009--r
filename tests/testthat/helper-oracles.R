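# Independent oracles used across the test suite.  These re-derive expected
# quantities from first principles (enumeration, dense multivariate-normal
# densities, brute-force simulation) without touching the implementation
# paths they check.

## --- brute-force free-parameter enumeration -------------------------------
# Lists every parameter entry of the model implied by the design and filters
# by status, collapsing invariance equality groups.  Written against the
# measurement equations directly, independently of build_template().
oracle_free_count <- function(I, J, L, roles, mi) {
  eq_load <- mi %in% c("weak", "strong", "strict")
  eq_int <- mi %in% c("strong", "strict")
  eq_res <- mi == "strict"
  free_means <- mi %in% c("strong", "strict")
  groups <- character(0)
  note <- function(key, collapse) {
    groups <<- c(groups, if (collapse) key else paste(key, length(groups)))
  }
  n_struct_nonref <- sum(roles == "nonreference_structural")
  has_int <- any(roles == "interchangeable_set")
  for (j in seq_len(J)) for (l in seq_len(L)) {
    for (k in seq_along(roles)) {
      for (i in seq_len(I)) {
        ref <- roles[k] == "reference_structural"
        # state loading: fixed only for the reference scaling indicator
        if (!(ref && i == 1)) note(sprintf("lamS %d %d %d", i, j, k), eq_load)
        if (roles[k] == "nonreference_structural" && i > 1) {
          note(sprintf("lamM %d %d %d", i, j, k), eq_load)
        }
        if (roles[k] == "interchangeable_set" && i > 1) {
          note(sprintf("lamCM %d %d", i, j), eq_load)
          note(sprintf("lamUM %d %d", i, j), eq_load)
        }
        note(sprintf("alpha %d %d %d", i, j, k), eq_int)
        note(sprintf("theta %d %d %d", i, j, k), eq_res)
      }
    }
    if (free_means && l > 1) note(sprintf("mean %d %d", j, l), FALSE)
  }
  nS <- J * L
  nM <- J * L * n_struct_nonref
  nCM <- if (has_int) J * L else 0
  nUM <- nCM
  n_cov <- function(m) m * (m - 1) / 2
  q_method <- nM + nCM
  n_phi_B <- nS + n_cov(nS) + q_method + n_cov(q_method)
  n_phi_W <- nUM + n_cov(nUM)
  length(unique(groups)) + n_phi_B + n_phi_W
}

## --- dense per-target multivariate-normal log-likelihood ------------------
dense_loglik <- function(data, template, params) {
  mom <- implied_moments(template, params)
  dense_loglik_moments(data, template, mom$mu_B, mom$Sigma_B, mom$Sigma_W)
}

dense_loglik_moments <- function(data, template, mu_B, Sigma_B, Sigma_W) {
  bn <- template$vars$name[template$vars$level == "between"]
  wn <- template$vars$name[template$vars$level == "rater"]
  nm <- c(bn, wn)
  mom <- list(mu_B = setNames(as.numeric(mu_B), nm),
              Sigma_B = `dimnames<-`(as.matrix(Sigma_B), list(nm, nm)),
              Sigma_W = `dimnames<-`(as.matrix(Sigma_W), list(wn, wn)))
  p_b <- length(bn); p_w <- length(wn)
  tot <- 0
  for (t in data$target_table$target_id) {
    x <- as.numeric(data$target_table[data$target_table$target_id == t, bn])
    if (p_w > 0) {
      ys <- as.matrix(data$rater_table[data$rater_table$target_id == t, wn,
                                       drop = FALSE])
      n <- nrow(ys)
    } else {
      ys <- NULL; n <- 0
    }
    z <- c(x, if (n > 0) as.numeric(t(ys)))
    muz <- c(mom$mu_B[bn], rep(mom$mu_B[wn], n))
    dim_z <- p_b + n * p_w
    S <- matrix(0, dim_z, dim_z)
    if (p_b > 0) S[1:p_b, 1:p_b] <- mom$Sigma_B[bn, bn]
    if (n > 0) {
      for (a in 1:n) {
        ia <- p_b + (a - 1) * p_w + 1:p_w
        if (p_b > 0) {
          S[1:p_b, ia] <- mom$Sigma_B[bn, wn]
          S[ia, 1:p_b] <- mom$Sigma_B[wn, bn]
        }
        for (b in 1:n) {
          ib <- p_b + (b - 1) * p_w + 1:p_w
          S[ia, ib] <- mom$Sigma_B[wn, wn] + (a == b) * mom$Sigma_W
        }
      }
    }
    ch <- chol(S)
    r <- z - muz
    tot <- tot - 0.5 * (dim_z * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          sum(backsolve(ch, r, transpose = TRUE)^2))
  }
  tot
}

## --- shortcut designs ------------------------------------------------------
design_full <- function(L = 2, J = 1, n_targets = 500, n_raters = 10, I = 3) {
  design_spec(I, J, c("reference_structural", "nonreference_structural",
                      "interchangeable_set"), L, n_targets, n_raters)
}

design_ri <- function(L = 1, J = 1, n_targets = 100, n_raters = 3, I = 3) {
  design_spec(I, J, c("reference_structural", "interchangeable_set"),
              L, n_targets, n_raters)
}

design_ref_only <- function(L = 2, J = 1, n_targets = 100, I = 3) {
  design_spec(I, J, "reference_structural", L, n_targets)
}

## random valid parameter set for property tests
random_params <- function(design, seed) {
  set.seed(seed)
  sk <- lscom:::lscom_skeleton(design)
  qB <- nrow(sk$factors_B); qW <- nrow(sk$factors_W)
  p <- nrow(sk$vars); p_w <- sk$p_w
  rand_psd <- function(q) {
    if (!q) return(matrix(0, 0, 0))
    A <- matrix(rnorm(q * (q + 2)), q + 2, q)
    crossprod(A) / (q + 2)
  }
  Phi_B <- rand_psd(qB)
  is_state <- sk$factors_B$type == "S"
  Phi_B[is_state, !is_state] <- 0
  Phi_B[!is_state, is_state] <- 0
  Lambda_B <- matrix(0, p, qB)
  Lambda_W <- matrix(0, p_w, qW)
  theta_B <- numeric(p); theta_W <- numeric(p_w)
  wnames <- sk$vars$name[sk$vars$level == "rater"]
  for (v in seq_len(p)) {
    j <- sk$vars$j[v]; k <- sk$vars$k[v]; l <- sk$vars$l[v]
    role <- sk$vars$role[v]
    Lambda_B[v, match(lscom:::factor_label("S", j, 1, l), sk$factors_B$name)] <-
      runif(1, 0.4, 1.3)
    if (role == "nonreference_structural") {
      Lambda_B[v, match(lscom:::factor_label("M", j, k, l), sk$factors_B$name)] <-
        runif(1, 0.3, 1.2)
    }
    if (role == "interchangeable_set") {
      Lambda_B[v, match(lscom:::factor_label("CM", j, k, l), sk$factors_B$name)] <-
        runif(1, 0.3, 1.2)
      w <- match(sk$vars$name[v], wnames)
      Lambda_W[w, match(lscom:::factor_label("UM", j, k, l), sk$factors_W$name)] <-
        runif(1, 0.3, 1.2)
      theta_W[w] <- runif(1, 0.1, 0.5)
    } else {
      theta_B[v] <- runif(1, 0.1, 0.5)
    }
  }
  means <- ifelse(sk$factors_B$type == "S" & sk$factors_B$l > 1,
                  rnorm(qB, 0, 0.5), 0)
  parameter_set(design, Lambda_B, Lambda_W, alpha = rnorm(p, 0.3, 0.3),
                factor_means = means, Phi_B = Phi_B, Phi_W = rand_psd(qW),
                theta_B = theta_B, theta_W = theta_W)
}

## sufficient statistics whose sample moments equal the implied moments
make_exact_stats <- function(template, params, T_n, n_r) {
  ## sufficient statistics whose sample moments equal the implied moments
  mom <- implied_moments(template, params)
  p <- length(mom$mu_B); p_w <- nrow(mom$Sigma_W); p_b <- p - p_w
  V <- mom$Sigma_B
  if (p_w > 0) {
    wi <- (p_b + 1):p
    V[wi, wi] <- V[wi, wi] + mom$Sigma_W / n_r
  }
  d <- T_n * (n_r - 1)
  structure(list(
    groups = list(list(T = T_n, n = if (p_w > 0) n_r else 0,
                       d = if (p_w > 0) d else 0,
                       SW = if (p_w > 0) d * mom$Sigma_W
                            else matrix(0, 0, 0),
                       SB = T_n * V, mean = mom$mu_B)),
    p = p, p_b = p_b, p_w = p_w, n_targets = T_n,
    n_raters_total = if (p_w > 0) T_n * n_r else 0,
    cluster_sizes = rep(if (p_w > 0) n_r else 0L, T_n),
    var_names = names(mom$mu_B), grand_mean = mom$mu_B,
    cov_between = V, var_within = diag(mom$Sigma_W)),
    class = "lscom_stats")
}

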
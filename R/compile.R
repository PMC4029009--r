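# Compilation of a template into the unconstrained estimation
# parameterization: one theta entry per free parameter group, with loadings,
# intercepts and latent means entering directly, residual variances on the
# log scale, and each free latent covariance block through its log-Cholesky
# factor.  The natural-parameter vector (what users see: loadings, variances,
# covariances, ...) has the same length and ordering as theta; covariance
# blocks map blockwise.

id_kinds <- c("loading_S", "loading_M", "loading_CM", "loading_UM",
              "intercept", "latent_mean")
log_kinds <- c("resid_B", "resid_W")
cov_kinds <- c("var_B", "cov_B", "var_W", "cov_W")

type12 <- c(loading_S = "loading_S", loading_CM = "loading_CM",
            loading_M = "loading_M", cov_B = "cov_L2",
            latent_mean = "latent_mean", intercept = "intercept",
            var_B = "var_L2", resid_B = "resid_L2",
            loading_UM = "loading_UM", var_W = "var_L1",
            cov_W = "cov_L1", resid_W = "resid_L1")

# connected components of factors linked by free covariances; every
# component must be a complete clique of free entries for the Cholesky
# parameterization to be a bijection onto the free set
cov_blocks <- function(tp, factors, var_kind, cov_kind) {
  nf <- nrow(factors)
  if (!nf) return(list())
  if (any(tp$kind == var_kind & tp$status == "fixed")) {
    stop("fixed latent variances are not supported by the estimation ",
         "parameterization", call. = FALSE)
  }
  if (any(tp$kind == cov_kind & tp$status == "fixed" &
            !is.na(tp$value) & tp$value != 0)) {
    stop("fixed nonzero latent covariances are not supported", call. = FALSE)
  }
  parent <- seq_len(nf)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  covs <- tp[tp$kind == cov_kind & tp$status == "free", , drop = FALSE]
  for (r in seq_len(nrow(covs))) {
    a <- match(covs$row[r], factors$name)
    b <- match(covs$col[r], factors$name)
    parent[find(a)] <- find(b)
  }
  roots <- vapply(seq_len(nf), find, integer(1))
  comps <- split(seq_len(nf), roots)
  comps <- comps[order(vapply(comps, min, integer(1)))]
  free_cov <- paste(covs$row, covs$col)
  for (comp in comps) {
    comp <- sort(comp)
    if (length(comp) > 1) {
      pairs <- t(combn(comp, 2))
      want <- paste(factors$name[pairs[, 1]], factors$name[pairs[, 2]])
      if (!all(want %in% free_cov)) {
        stop("free latent covariance pattern is not a union of complete ",
             "blocks; this pattern cannot be estimated with the ",
             "block-Cholesky parameterization", call. = FALSE)
      }
    }
  }
  lapply(comps, sort)
}

compile_model <- function(template) {
  stopifnot(inherits(template, "lscom_template"))
  tp <- template$params
  vars <- template$vars
  fB <- template$factors_B; fW <- template$factors_W
  p <- nrow(vars); p_b <- template$p_b; p_w <- template$p_w
  qB <- nrow(fB); qW <- nrow(fW)
  wnames <- vars$name[vars$level == "rater"]

  free <- tp$status == "free"
  nat_label <- character(0); nat_kind <- character(0)
  group_of <- character(0)

  take <- function(kinds) {
    sel <- free & tp$kind %in% kinds
    grp <- tp$group[sel]
    first <- !duplicated(grp)
    list(labels = tp$label[sel][first], kinds = tp$kind[sel][first],
         groups = grp[first])
  }
  ids <- take(id_kinds)
  logs <- take(log_kinds)
  n_id <- length(ids$groups); n_log <- length(logs$groups)
  theta_of_group <- setNames(seq_len(n_id + n_log) - 1L,
                             c(ids$groups, logs$groups))
  nat_label <- c(ids$labels, logs$labels)
  nat_kind <- c(ids$kinds, logs$kinds)

  next_theta <- n_id + n_log
  build_blocks <- function(factors, var_kind, cov_kind, phi_prefix) {
    comps <- cov_blocks(tp, factors, var_kind, cov_kind)
    blocks <- list()
    for (comp in comps) {
      m <- length(comp)
      th <- next_theta + seq_len(m * (m + 1) / 2) - 1L
      next_theta <<- next_theta + m * (m + 1) / 2
      labs <- character(0); kinds <- character(0)
      for (cc in seq_len(m)) {
        for (rr in cc:m) {
          if (rr == cc) {
            labs <- c(labs, sprintf("%s[%s]", phi_prefix, factors$name[comp[cc]]))
            kinds <- c(kinds, var_kind)
          } else {
            labs <- c(labs, sprintf("%s[%s;%s]", phi_prefix,
                                    factors$name[comp[cc]],
                                    factors$name[comp[rr]]))
            kinds <- c(kinds, cov_kind)
          }
        }
      }
      nat_label <<- c(nat_label, labs)
      nat_kind <<- c(nat_kind, kinds)
      blocks[[length(blocks) + 1L]] <- list(idx = as.integer(comp - 1L),
                                            th = as.integer(th))
    }
    blocks
  }
  blocks_B <- build_blocks(fB, "var_B", "cov_B", "phi_B")
  blocks_W <- if (qW) build_blocks(fW, "var_W", "cov_W", "phi_W") else list()
  n_theta <- next_theta

  ## position maps -----------------------------------------------------
  LB0 <- matrix(0, p, qB); LW0 <- matrix(0, max(p_w, 0), max(qW, 0))
  a0 <- numeric(p); m0 <- numeric(qB); tB0 <- numeric(p); tW0 <- numeric(p_w)
  lb_pos <- lb_th <- lw_pos <- lw_th <- integer(0)
  a_pos <- a_th <- m_pos <- m_th <- integer(0)
  tb_pos <- tb_th <- tw_pos <- tw_th <- integer(0)

  for (r in seq_len(nrow(tp))) {
    kind <- tp$kind[r]
    if (kind %in% c("loading_S", "loading_M", "loading_CM")) {
      vi <- match(tp$row[r], vars$name); fi <- match(tp$col[r], fB$name)
      pos <- (fi - 1L) * p + (vi - 1L)
      if (free[r]) {
        lb_pos <- c(lb_pos, pos)
        lb_th <- c(lb_th, theta_of_group[[tp$group[r]]])
      } else LB0[vi, fi] <- tp$value[r]
    } else if (kind == "loading_UM") {
      wi <- match(tp$row[r], wnames); fi <- match(tp$col[r], fW$name)
      pos <- (fi - 1L) * p_w + (wi - 1L)
      if (free[r]) {
        lw_pos <- c(lw_pos, pos)
        lw_th <- c(lw_th, theta_of_group[[tp$group[r]]])
      } else LW0[wi, fi] <- tp$value[r]
    } else if (kind == "intercept") {
      vi <- match(tp$row[r], vars$name)
      if (free[r]) {
        a_pos <- c(a_pos, vi - 1L)
        a_th <- c(a_th, theta_of_group[[tp$group[r]]])
      } else a0[vi] <- tp$value[r]
    } else if (kind == "latent_mean") {
      fi <- match(tp$row[r], fB$name)
      if (free[r]) {
        m_pos <- c(m_pos, fi - 1L)
        m_th <- c(m_th, theta_of_group[[tp$group[r]]])
      } else m0[fi] <- tp$value[r]
    } else if (kind == "resid_B") {
      vi <- match(tp$row[r], vars$name)
      if (free[r]) {
        tb_pos <- c(tb_pos, vi - 1L)
        tb_th <- c(tb_th, theta_of_group[[tp$group[r]]])
      } else tB0[vi] <- tp$value[r]
    } else if (kind == "resid_W") {
      wi <- match(tp$row[r], wnames)
      if (free[r]) {
        tw_pos <- c(tw_pos, wi - 1L)
        tw_th <- c(tw_th, theta_of_group[[tp$group[r]]])
      } else tW0[wi] <- tp$value[r]
    }
  }

  cpp <- list(p = p, p_b = p_b, p_w = p_w, qB = qB, qW = qW,
              n_theta = as.integer(n_theta),
              LB0 = LB0, LW0 = LW0, a0 = a0, m0 = m0, tB0 = tB0, tW0 = tW0,
              lb_pos = lb_pos, lb_th = lb_th, lw_pos = lw_pos, lw_th = lw_th,
              a_pos = a_pos, a_th = a_th, m_pos = m_pos, m_th = m_th,
              tb_pos = tb_pos, tb_th = tb_th, tw_pos = tw_pos, tw_th = tw_th,
              blocks_B = blocks_B, blocks_W = blocks_W)
  structure(list(template = template, cpp = cpp, n_theta = n_theta,
                 nat = data.frame(label = nat_label, kind = nat_kind,
                                  type = unname(type12[nat_kind]),
                                  stringsAsFactors = FALSE)),
            class = "lscom_compiled")
}

phi_from_theta <- function(blocks, theta, q) {
  Phi <- matrix(0, q, q)
  for (blk in blocks) {
    m <- length(blk$idx)
    L <- matrix(0, m, m)
    pos <- 1L
    for (cc in seq_len(m)) {
      for (rr in cc:m) {
        v <- theta[blk$th[pos] + 1L]
        L[rr, cc] <- if (rr == cc) exp(v) else v
        pos <- pos + 1L
      }
    }
    Phi[blk$idx + 1L, blk$idx + 1L] <- L %*% t(L)
  }
  Phi
}

theta_to_matrices <- function(cm, theta) {
  cp <- cm$cpp
  LB <- cp$LB0; LB[cp$lb_pos + 1L] <- theta[cp$lb_th + 1L]
  LW <- cp$LW0
  if (length(cp$lw_pos)) LW[cp$lw_pos + 1L] <- theta[cp$lw_th + 1L]
  a <- cp$a0; a[cp$a_pos + 1L] <- theta[cp$a_th + 1L]
  m <- cp$m0; if (length(cp$m_pos)) m[cp$m_pos + 1L] <- theta[cp$m_th + 1L]
  tB <- cp$tB0; tB[cp$tb_pos + 1L] <- exp(theta[cp$tb_th + 1L])
  tW <- cp$tW0
  if (length(cp$tw_pos)) tW[cp$tw_pos + 1L] <- exp(theta[cp$tw_th + 1L])
  list(Lambda_B = LB, Lambda_W = LW, alpha = a, factor_means = m,
       Phi_B = phi_from_theta(cp$blocks_B, theta, cp$qB),
       Phi_W = phi_from_theta(cp$blocks_W, theta, cp$qW),
       theta_B = tB, theta_W = tW)
}

theta_to_params <- function(cm, theta) {
  mats <- theta_to_matrices(cm, theta)
  parameter_set(cm$template$design, mats$Lambda_B, mats$Lambda_W, mats$alpha,
                mats$factor_means, mats$Phi_B, mats$Phi_W, mats$theta_B,
                mats$theta_W)
}

vech_block <- function(Phi, idx) {
  m <- length(idx)
  out <- numeric(m * (m + 1) / 2)
  pos <- 1L
  for (cc in seq_len(m)) {
    for (rr in cc:m) {
      out[pos] <- Phi[idx[rr] + 1L, idx[cc] + 1L]
      pos <- pos + 1L
    }
  }
  out
}

natural_from_theta <- function(cm, theta) {
  mats <- theta_to_matrices(cm, theta)
  natural_from_matrices(cm, mats)
}

natural_from_matrices <- function(cm, mats) {
  cp <- cm$cpp
  out <- numeric(cm$n_theta)
  nat <- cm$nat
  idl <- nat$kind %in% id_kinds
  lgl <- nat$kind %in% log_kinds
  n_id <- sum(idl); n_log <- sum(lgl)
  ## identity and log entries occupy theta slots 0..n_id+n_log-1 in order
  vals <- numeric(n_id + n_log)
  fill <- function(pos, th, source) {
    sel <- th < n_id + n_log
    vals[th[sel] + 1L] <<- source[pos[sel] + 1L]
  }
  fill(cp$lb_pos, cp$lb_th, as.numeric(mats$Lambda_B))
  if (length(cp$lw_pos)) fill(cp$lw_pos, cp$lw_th, as.numeric(mats$Lambda_W))
  fill(cp$a_pos, cp$a_th, mats$alpha)
  if (length(cp$m_pos)) fill(cp$m_pos, cp$m_th, mats$factor_means)
  fill(cp$tb_pos, cp$tb_th, mats$theta_B)
  if (length(cp$tw_pos)) fill(cp$tw_pos, cp$tw_th, mats$theta_W)
  out[seq_len(n_id + n_log)] <- vals
  pos <- n_id + n_log
  for (blk in cp$blocks_B) {
    v <- vech_block(mats$Phi_B, blk$idx)
    out[pos + seq_along(v)] <- v
    pos <- pos + length(v)
  }
  for (blk in cp$blocks_W) {
    v <- vech_block(mats$Phi_W, blk$idx)
    out[pos + seq_along(v)] <- v
    pos <- pos + length(v)
  }
  setNames(out, nat$label)
}

natural_from_params <- function(cm, params) {
  natural_from_matrices(cm, params)
}

params_to_theta <- function(cm, params) {
  cp <- cm$cpp
  nat <- cm$nat
  n_id <- sum(nat$kind %in% id_kinds)
  n_log <- sum(nat$kind %in% log_kinds)
  theta <- numeric(cm$n_theta)
  natv <- natural_from_params(cm, params)
  theta[seq_len(n_id)] <- natv[seq_len(n_id)]
  theta[n_id + seq_len(n_log)] <- log(pmax(natv[n_id + seq_len(n_log)], 1e-8))
  chol_fill <- function(Phi, blocks) {
    for (blk in blocks) {
      sub <- Phi[blk$idx + 1L, blk$idx + 1L, drop = FALSE]
      L <- t(chol(sub))
      m <- length(blk$idx)
      pos <- 1L
      for (cc in seq_len(m)) {
        for (rr in cc:m) {
          theta[blk$th[pos] + 1L] <<- if (rr == cc) log(L[rr, cc]) else L[rr, cc]
          pos <- pos + 1L
        }
      }
    }
  }
  chol_fill(params$Phi_B, cp$blocks_B)
  if (params$p_w > 0) chol_fill(params$Phi_W, cp$blocks_W)
  theta
}
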
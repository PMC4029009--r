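#' @useDynLib lscom, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pchisq qchisq rnorm sd setNames var nlminb cov
#' @importFrom utils read.csv write.csv packageVersion combn
NULL

var_label <- function(i, j, k, l) sprintf("Y[%d.%d.%d.%d]", i, j, k, l)

factor_label <- function(type, j, k, l) {
  switch(type,
         S  = sprintf("S[%d.%d]", j, l),
         M  = sprintf("M[%d.%d.%d]", j, k, l),
         CM = sprintf("CM[%d.%d]", j, l),
         UM = sprintf("UM[%d.%d]", j, l))
}

# Observed-variable and latent-factor inventories implied by a design.
# Variable order is the package-wide convention: between-only variables first,
# then rater-level variables, each sorted by (l, k, j, i) (l slowest).
lscom_skeleton <- function(design) {
  I <- design$n_indicators; J <- design$n_constructs; L <- design$n_occasions
  roles <- design$methods
  var_rows <- function(ks) {
    if (!length(ks)) {
      return(data.frame(name = character(), i = integer(), j = integer(),
                        k = integer(), l = integer(), role = character(),
                        stringsAsFactors = FALSE))
    }
    g <- expand.grid(i = seq_len(I), j = seq_len(J), k = ks, l = seq_len(L))
    data.frame(name = var_label(g$i, g$j, g$k, g$l), i = g$i, j = g$j,
               k = g$k, l = g$l, role = roles[g$k], stringsAsFactors = FALSE)
  }
  struct_ks <- which(roles != "interchangeable_set")
  interch_k <- which(roles == "interchangeable_set")
  vars_b <- var_rows(struct_ks)
  vars_w <- var_rows(interch_k)
  vars_b$level <- rep("between", nrow(vars_b))
  vars_w$level <- rep("rater", nrow(vars_w))
  vars <- rbind(vars_b, vars_w)

  gS <- expand.grid(j = seq_len(J), l = seq_len(L))
  factors_B <- data.frame(name = factor_label("S", gS$j, 1L, gS$l),
                          type = "S", j = gS$j, k = 1L, l = gS$l,
                          stringsAsFactors = FALSE)
  nonref_ks <- which(roles == "nonreference_structural")
  if (length(nonref_ks)) {
    gM <- expand.grid(j = seq_len(J), k = nonref_ks, l = seq_len(L))
    factors_B <- rbind(factors_B,
                       data.frame(name = factor_label("M", gM$j, gM$k, gM$l),
                                  type = "M", j = gM$j, k = gM$k, l = gM$l,
                                  stringsAsFactors = FALSE))
  }
  factors_W <- data.frame(name = character(), type = character(),
                          j = integer(), k = integer(), l = integer(),
                          stringsAsFactors = FALSE)
  if (length(interch_k)) {
    gC <- expand.grid(j = seq_len(J), l = seq_len(L))
    factors_B <- rbind(factors_B,
                       data.frame(name = factor_label("CM", gC$j, interch_k, gC$l),
                                  type = "CM", j = gC$j, k = interch_k, l = gC$l,
                                  stringsAsFactors = FALSE))
    factors_W <- data.frame(name = factor_label("UM", gC$j, interch_k, gC$l),
                            type = "UM", j = gC$j, k = interch_k, l = gC$l,
                            stringsAsFactors = FALSE)
  }
  list(vars = vars, factors_B = factors_B, factors_W = factors_W,
       p_b = nrow(vars_b), p_w = nrow(vars_w))
}

param_row <- function(label, kind, i = NA, j = NA, k = NA, l = NA,
                      row = NA, col = NA, status = "free", value = NA,
                      group = NA) {
  data.frame(label = label, kind = kind, i = i, j = j, k = k, l = l,
             row = row, col = col, status = status, value = value,
             group = if (is.na(group) && status == "free") label else group,
             stringsAsFactors = FALSE)
}

drop_l <- function(fmt_label) sub("\\.([0-9]+)(\\]+)$", ".*\\2", fmt_label)

#' Build an LS-COM model template
#'
#' Expands a measurement design into the complete parameter inventory of the
#' latent-state combination-of-methods model: factor loadings, intercepts,
#' latent state means, latent covariance matrices at both levels, and residual
#' variances, each marked free, fixed, or constrained equal across occasions.
#'
#' Reference-method indicators load only on their latent state factor;
#' indicators of a structurally different non-reference method additionally
#' load on a target-level method factor; indicators of the interchangeable
#' rater set load on the state factor, a target-level common method factor,
#' and a rater-level unique method factor.  Each latent factor is scaled by
#' fixing the loading of its first indicator to one (for state factors: the
#' reference method's first indicator); method factors have mean zero by
#' construction.
#'
#' Measurement invariance is imposed as nested equality constraints across
#' occasions: `"weak"` equates loadings, `"strong"` additionally equates
#' intercepts and frees the latent state means at occasions beyond the first
#' (the first occasion's mean is fixed to zero so the remaining means are
#' mean change relative to occasion one), `"strict"` additionally equates
#' residual variances.
#'
#' @param design An [design_spec()] object.
#' @param mi Measurement-invariance level: `"configural"`, `"weak"`,
#'   `"strong"` (default) or `"strict"`.
#' @param policy A [correlation_policy()] object.
#' @return An object of class `lscom_template` with the parameter table in
#'   `$params` and variable/factor inventories.
#' @examples
#' d <- design_spec(3, 1, c("reference_structural", "interchangeable_set"),
#'                  n_occasions = 2, n_targets = 200, n_raters = 5)
#' tpl <- build_template(d, mi = "strong")
#' count_free_parameters(tpl)
#' @export
build_template <- function(design, mi = "strong", policy = correlation_policy()) {
  stopifnot(inherits(design, "lscom_design"))
  mi <- check_mi(mi)
  stopifnot(inherits(policy, "lscom_policy"))
  sk <- lscom_skeleton(design)
  vars <- sk$vars
  eq_load <- mi %in% c("weak", "strong", "strict")
  eq_int  <- mi %in% c("strong", "strict")
  eq_res  <- mi == "strict"
  free_means <- mi %in% c("strong", "strict")

  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  ## loadings -----------------------------------------------------------
  for (v in seq_len(nrow(vars))) {
    i <- vars$i[v]; j <- vars$j[v]; k <- vars$k[v]; l <- vars$l[v]
    role <- vars$role[v]
    lab <- sprintf("lambda_S[%d.%d.%d.%d]", i, j, k, l)
    fixS <- role == "reference_structural" && i == 1L
    add(param_row(lab, "loading_S", i, j, k, l,
                  row = vars$name[v], col = factor_label("S", j, 1L, l),
                  status = if (fixS) "fixed" else "free",
                  value = if (fixS) 1 else NA,
                  group = if (!fixS && eq_load) drop_l(lab) else NA))
    if (role == "nonreference_structural") {
      lab <- sprintf("lambda_M[%d.%d.%d.%d]", i, j, k, l)
      add(param_row(lab, "loading_M", i, j, k, l,
                    row = vars$name[v], col = factor_label("M", j, k, l),
                    status = if (i == 1L) "fixed" else "free",
                    value = if (i == 1L) 1 else NA,
                    group = if (i > 1L && eq_load) drop_l(lab) else NA))
    }
    if (role == "interchangeable_set") {
      lab <- sprintf("lambda_CM[%d.%d.%d.%d]", i, j, k, l)
      add(param_row(lab, "loading_CM", i, j, k, l,
                    row = vars$name[v], col = factor_label("CM", j, k, l),
                    status = if (i == 1L) "fixed" else "free",
                    value = if (i == 1L) 1 else NA,
                    group = if (i > 1L && eq_load) drop_l(lab) else NA))
      lab <- sprintf("lambda_UM[%d.%d.%d.%d]", i, j, k, l)
      add(param_row(lab, "loading_UM", i, j, k, l,
                    row = vars$name[v], col = factor_label("UM", j, k, l),
                    status = if (i == 1L) "fixed" else "free",
                    value = if (i == 1L) 1 else NA,
                    group = if (i > 1L && eq_load) drop_l(lab) else NA))
    }
  }

  ## intercepts ---------------------------------------------------------
  for (v in seq_len(nrow(vars))) {
    lab <- sprintf("alpha[%d.%d.%d.%d]", vars$i[v], vars$j[v], vars$k[v], vars$l[v])
    add(param_row(lab, "intercept", vars$i[v], vars$j[v], vars$k[v], vars$l[v],
                  row = vars$name[v],
                  group = if (eq_int) drop_l(lab) else NA))
  }

  ## latent state means -------------------------------------------------
  fB <- sk$factors_B
  for (f in which(fB$type == "S")) {
    j <- fB$j[f]; l <- fB$l[f]
    lab <- sprintf("mean_S[%d.%d]", j, l)
    free <- free_means && l > 1L
    add(param_row(lab, "latent_mean", j = j, l = l, row = fB$name[f],
                  status = if (free) "free" else "fixed",
                  value = if (free) NA else 0))
  }

  ## Level-2 latent covariance matrix ----------------------------------
  nB <- nrow(fB)
  for (a in seq_len(nB)) {
    for (b in a:nB) {
      fa <- fB[a, ]; fb <- fB[b, ]
      if (a == b) {
        add(param_row(sprintf("phi_B[%s]", fa$name), "var_B",
                      j = fa$j, k = fa$k, l = fa$l,
                      row = fa$name, col = fa$name))
        next
      }
      both_S <- fa$type == "S" && fb$type == "S"
      both_M <- fa$type %in% c("M", "CM") && fb$type %in% c("M", "CM")
      free <- (both_S && policy$state_state) || (both_M && policy$method_method_L2)
      add(param_row(sprintf("phi_B[%s;%s]", fa$name, fb$name), "cov_B",
                    row = fa$name, col = fb$name,
                    status = if (free) "free" else "fixed",
                    value = if (free) NA else 0))
    }
  }

  ## Level-1 latent covariance matrix ----------------------------------
  fW <- sk$factors_W
  nW <- nrow(fW)
  if (nW) {
    for (a in seq_len(nW)) {
      for (b in a:nW) {
        if (a == b) {
          add(param_row(sprintf("phi_W[%s]", fW$name[a]), "var_W",
                        j = fW$j[a], k = fW$k[a], l = fW$l[a],
                        row = fW$name[a], col = fW$name[a]))
        } else {
          free <- policy$method_method_L1
          add(param_row(sprintf("phi_W[%s;%s]", fW$name[a], fW$name[b]), "cov_W",
                        row = fW$name[a], col = fW$name[b],
                        status = if (free) "free" else "fixed",
                        value = if (free) NA else 0))
        }
      }
    }
  }

  ## residual variances -------------------------------------------------
  for (v in seq_len(nrow(vars))) {
    between <- vars$level[v] == "between"
    lab <- sprintf("theta_%s[%s]", if (between) "B" else "W", vars$name[v])
    add(param_row(lab, if (between) "resid_B" else "resid_W",
                  vars$i[v], vars$j[v], vars$k[v], vars$l[v],
                  row = vars$name[v],
                  group = if (eq_res) drop_l(lab) else NA))
  }

  params <- do.call(rbind, rows)
  rownames(params) <- NULL
  structure(list(design = design, mi = mi, policy = policy,
                 vars = vars, factors_B = fB, factors_W = fW,
                 p_b = sk$p_b, p_w = sk$p_w, params = params),
            class = "lscom_template")
}

#' Count free parameters of a template
#'
#' Counts parameter entries with free status; entries tied by an equality
#' group count once.
#'
#' @param template An [build_template()] object.
#' @return Integer count.
#' @export
count_free_parameters <- function(template) {
  stopifnot(inherits(template, "lscom_template"))
  p <- template$params
  length(unique(p$group[p$status == "free"]))
}

#' @export
print.lscom_template <- function(x, ...) {
  cat("LS-COM model template\n")
  cat(sprintf("  invariance level : %s\n", x$mi))
  cat(sprintf("  observed vars    : %d between-only, %d rater-level\n",
              x$p_b, x$p_w))
  tb <- table(x$factors_B$type)
  cat(sprintf("  Level-2 factors  : %s\n",
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  cat(sprintf("  Level-1 factors  : UM=%d\n", nrow(x$factors_W)))
  cat(sprintf("  parameters       : %d entries, %d free\n",
              nrow(x$params), count_free_parameters(x)))
  invisible(x)
}

#' Serialize a template to a structured text file
#'
#' Writes the design, invariance level, correlation policy and the full
#' parameter inventory as YAML so a template round-trips exactly.
#'
#' @param template A template.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "lscom_template"))
  d <- template$design
  obj <- list(
    design = list(n_indicators = d$n_indicators, n_constructs = d$n_constructs,
                  methods = d$methods, n_occasions = d$n_occasions,
                  n_targets = d$n_targets, n_raters = d$n_raters),
    mi = template$mi,
    policy = list(state_state = template$policy$state_state,
                  method_method_L2 = template$policy$method_method_L2,
                  method_method_L1 = template$policy$method_method_L1),
    params = lapply(seq_len(nrow(template$params)), function(r) {
      as.list(template$params[r, ])
    }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a serialized template
#'
#' @param path File written by [write_template()].
#' @return An `lscom_template`.
#' @export
read_template <- function(path) {
  obj <- yaml::read_yaml(path)
  d <- obj$design
  design <- design_spec(d$n_indicators, d$n_constructs, unlist(d$methods),
                        d$n_occasions, d$n_targets, unlist(d$n_raters))
  tpl <- build_template(design, mi = obj$mi,
                        policy = correlation_policy(obj$policy$state_state,
                                                    obj$policy$method_method_L2,
                                                    obj$policy$method_method_L1))
  stored <- do.call(rbind, lapply(obj$params, function(p) {
    p[sapply(p, is.null)] <- NA
    as.data.frame(p, stringsAsFactors = FALSE)
  }))
  rownames(stored) <- NULL
  if (!identical(dim(stored), dim(tpl$params)) ||
      !all(stored$label == tpl$params$label)) {
    stop("stored parameter inventory does not match its design; ",
         "file may be corrupted", call. = FALSE)
  }
  tpl
}
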
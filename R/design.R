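#' Specify an LS-COM measurement design
#'
#' A design describes the shape of a longitudinal multitrait-multimethod
#' measurement study: how many indicators each trait-method unit has, how many
#' constructs and occasions are measured, which methods are involved and what
#' their sampling role is, and the sample sizes at the target (Level 2) and
#' rater (Level 1) level.
#'
#' Methods come in three roles: exactly one `"reference_structural"` method
#' anchors the latent state factors; any number of
#' `"nonreference_structural"` methods (e.g., a parent report) contribute a
#' target-level method factor each; at most one `"interchangeable_set"`
#' (e.g., multiple peer raters per target) contributes a target-level common
#' method factor and a rater-level unique method factor and turns the data
#' into a two-level rater-within-target structure.
#'
#' @param n_indicators Number of indicators per trait-method unit (\eqn{I \ge 2}).
#' @param n_constructs Number of constructs \eqn{J \ge 1}.
#' @param methods Character vector of method roles, in method order
#'   (method index `k` follows this order).  The first method must be the
#'   reference; see Details.
#' @param n_occasions Number of measurement occasions \eqn{L \ge 1}.
#' @param n_targets Number of Level-2 units (targets).
#' @param n_raters Number of interchangeable raters per target: a single
#'   number (balanced design) or an integer vector of length `n_targets`.
#'   Ignored (and may be 0) when no interchangeable set is present.
#' @return An object of class `lscom_design`.
#' @examples
#' design_spec(3, 1, c("reference_structural", "interchangeable_set"),
#'             n_occasions = 2, n_targets = 100, n_raters = 5)
#' @export
design_spec <- function(n_indicators, n_constructs, methods,
                        n_occasions, n_targets = 100, n_raters = 0) {
  roles <- c("reference_structural", "nonreference_structural",
             "interchangeable_set")
  methods <- match.arg(methods, roles, several.ok = TRUE)
  stopifnot(length(n_indicators) == 1, length(n_constructs) == 1,
            length(n_occasions) == 1, length(n_targets) == 1)
  if (n_indicators < 2) {
    stop("at least 2 indicators per trait-method unit are required; ",
         "method factors with a single indicator are not identified here",
         call. = FALSE)
  }
  if (n_constructs < 1 || n_occasions < 1 || n_targets < 1) {
    stop("n_constructs, n_occasions and n_targets must be >= 1", call. = FALSE)
  }
  n_ref <- sum(methods == "reference_structural")
  if (n_ref == 0 && any(methods == "interchangeable_set")) {
    stop("choosing the interchangeable set as reference method is not ",
         "implemented; exactly one structurally different method must have ",
         "role 'reference_structural'", call. = FALSE)
  }
  if (n_ref != 1) {
    stop("exactly one method must have role 'reference_structural'",
         call. = FALSE)
  }
  if (methods[1] != "reference_structural") {
    stop("the reference method must be listed first (method index k = 1)",
         call. = FALSE)
  }
  if (sum(methods == "interchangeable_set") > 1) {
    stop("at most one interchangeable method set is supported", call. = FALSE)
  }
  has_interch <- any(methods == "interchangeable_set")
  if (has_interch) {
    if (length(n_raters) == 1) {
      if (n_raters < 2) {
        stop("n_raters must be >= 2 when an interchangeable set is present",
             call. = FALSE)
      }
    } else {
      if (length(n_raters) != n_targets) {
        stop("per-target n_raters must have length n_targets", call. = FALSE)
      }
      if (any(n_raters < 2)) {
        stop("every target needs >= 2 raters when an interchangeable set ",
             "is present", call. = FALSE)
      }
    }
  }
  structure(
    list(n_indicators = as.integer(n_indicators),
         n_constructs = as.integer(n_constructs),
         methods = methods,
         n_occasions = as.integer(n_occasions),
         n_targets = as.integer(n_targets),
         n_raters = as.integer(n_raters)),
    class = "lscom_design")
}

#' @export
print.lscom_design <- function(x, ...) {
  cat("LS-COM measurement design\n")
  cat(sprintf("  indicators per TMU : %d\n", x$n_indicators))
  cat(sprintf("  constructs         : %d\n", x$n_constructs))
  cat(sprintf("  occasions          : %d\n", x$n_occasions))
  cat(sprintf("  methods (k order)  : %s\n", paste(x$methods, collapse = ", ")))
  cat(sprintf("  targets (L2)       : %d\n", x$n_targets))
  if (design_has_interchangeable(x)) {
    nr <- x$n_raters
    cat(sprintf("  raters per target  : %s\n",
                if (length(nr) == 1) as.character(nr)
                else sprintf("%d-%d (unbalanced)", min(nr), max(nr))))
  }
  invisible(x)
}

design_has_interchangeable <- function(design) {
  any(design$methods == "interchangeable_set")
}

design_interch_index <- function(design) {
  k <- which(design$methods == "interchangeable_set")
  if (length(k)) k else NA_integer_
}

#' Correlation policy for latent factors
#'
#' Controls which latent covariances are freely estimated.  State factors may
#' covary across all construct/occasion pairs; Level-2 method factors (M and
#' CM) may covary among themselves (including M-with-CM); Level-1 unique
#' method factors may covary among themselves.  State-method covariances,
#' cross-level covariances, and error covariances are structurally zero in
#' the LS-COM model and cannot be freed.
#'
#' @param state_state Allow covariances among latent state factors.
#' @param method_method_L2 Allow covariances among Level-2 method factors
#'   (M and CM, including cross-method pairs).
#' @param method_method_L1 Allow covariances among Level-1 unique method
#'   factors.
#' @return An object of class `lscom_policy`.
#' @export
correlation_policy <- function(state_state = TRUE,
                               method_method_L2 = TRUE,
                               method_method_L1 = TRUE) {
  structure(list(state_state = isTRUE(state_state),
                 method_method_L2 = isTRUE(method_method_L2),
                 method_method_L1 = isTRUE(method_method_L1),
                 state_method = FALSE,
                 cross_level = FALSE,
                 error_error = FALSE),
            class = "lscom_policy")
}

#' @export
print.lscom_policy <- function(x, ...) {
  cat("LS-COM correlation policy\n")
  cat("  state-state       :", if (x$state_state) "free" else "zero", "\n")
  cat("  method-method (L2):", if (x$method_method_L2) "free" else "zero", "\n")
  cat("  method-method (L1):", if (x$method_method_L1) "free" else "zero", "\n")
  cat("  state-method, cross-level, error-error: structurally zero\n")
  invisible(x)
}

mi_levels <- c("configural", "weak", "strong", "strict")

check_mi <- function(mi) match.arg(mi, mi_levels)
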
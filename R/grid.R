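#' Build the design for a Monte-Carlo grid cell
#'
#' Grid cells describe models by counts: 2 methods means a reference
#' structural method plus the interchangeable rater set; 3 methods adds a
#' structurally different non-reference method.  Three indicators per
#' trait-method unit are used throughout the simulation designs.
#'
#' @param n_constructs Number of constructs.
#' @param n_methods 2 or 3.
#' @param n_occasions Number of occasions.
#' @param n_targets Level-2 sample size.
#' @param n_raters Raters per target.
#' @param n_indicators Indicators per trait-method unit (default 3).
#' @return An [design_spec()] object.
#' @export
condition_design <- function(n_constructs, n_methods, n_occasions,
                             n_targets = 100, n_raters = 2,
                             n_indicators = 3) {
  methods <- switch(as.character(n_methods),
    "2" = c("reference_structural", "interchangeable_set"),
    "3" = c("reference_structural", "nonreference_structural",
            "interchangeable_set"),
    stop("n_methods must be 2 or 3", call. = FALSE))
  design_spec(n_indicators, n_constructs, methods, n_occasions,
              n_targets, n_raters)
}

#' Monte-Carlo condition grid
#'
#' The default levels form the full factorial studied for the LS-COM model:
#' 1 or 2 constructs, 2 or 3 methods, 2-4 occasions, low or high consistency,
#' 2/5/10/20 raters per target, and 100/250/500 targets
#' (2 x 2 x 2 x 3 x 4 x 3 = 288 cells).
#'
#' @param constructs,methods,occasions,consistency,n_raters,n_targets Factor
#'   levels of the grid.
#' @param n_indicators Indicators per trait-method unit.
#' @return An object of class `lscom_grid` (a list of factor levels).
#' @export
condition_grid <- function(constructs = c(1, 2), methods = c(2, 3),
                           occasions = c(2, 3, 4),
                           consistency = c("low", "high"),
                           n_raters = c(2, 5, 10, 20),
                           n_targets = c(100, 250, 500),
                           n_indicators = 3) {
  structure(list(constructs = constructs, methods = methods,
                 occasions = occasions, consistency = consistency,
                 n_raters = n_raters, n_targets = n_targets,
                 n_indicators = n_indicators),
            class = "lscom_grid")
}

#' Enumerate grid cells with feasibility
#'
#' Expands the full factorial and marks each cell infeasible when it has
#' fewer targets than free model parameters (counted on the strong-invariance
#' template for that cell's design), the constellation in which the model is
#' underidentified.
#'
#' @param grid A [condition_grid()].
#' @param mi Invariance level used for the free-parameter count.
#' @return A data.frame with one row per cell, the free-parameter count, and
#'   a logical `feasible` column.
#' @export
enumerate_conditions <- function(grid = condition_grid(), mi = "strong") {
  stopifnot(inherits(grid, "lscom_grid"))
  cells <- expand.grid(constructs = grid$constructs, methods = grid$methods,
                       occasions = grid$occasions,
                       consistency = grid$consistency,
                       n_raters = grid$n_raters, n_targets = grid$n_targets,
                       stringsAsFactors = FALSE)
  shapes <- unique(cells[c("constructs", "methods", "occasions")])
  shapes$free_parameters <- vapply(seq_len(nrow(shapes)), function(r) {
    design <- condition_design(shapes$constructs[r], shapes$methods[r],
                               shapes$occasions[r],
                               n_indicators = grid$n_indicators)
    count_free_parameters(build_template(design, mi = mi))
  }, integer(1))
  key <- function(d) paste(d$constructs, d$methods, d$occasions)
  cells$free_parameters <- shapes$free_parameters[match(key(cells), key(shapes))]
  cells$feasible <- cells$n_targets >= cells$free_parameters
  cells$condition_id <- seq_len(nrow(cells))
  cells
}
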
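# Dataset, report, and configuration I/O.  Delimited-text dialect: comma
# separator, period decimal, UTF-8, mandatory header row, canonical column
# labels Y[i.j.k.l] with target_id / rater_id keys.

config_hash <- function(x) {
  s <- yaml::as.yaml(x)
  h <- 7
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%x", as.integer(h))
}

provenance <- function(seed = NA, config = NULL) {
  list(package = "lscom",
       version = as.character(packageVersion("lscom")),
       seed = if (is.na(seed)) NULL else as.integer(seed),
       config_hash = if (is.null(config)) NULL else config_hash(config))
}

design_to_config <- function(design) {
  list(n_indicators = design$n_indicators, n_constructs = design$n_constructs,
       methods = as.list(design$methods), n_occasions = design$n_occasions,
       n_targets = design$n_targets, n_raters = as.list(design$n_raters))
}

design_from_config <- function(cfg) {
  need <- c("n_indicators", "n_constructs", "methods", "n_occasions",
            "n_targets")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("design config is missing key '", miss[1], "'", call. = FALSE)
  }
  design_spec(cfg$n_indicators, cfg$n_constructs, unlist(cfg$methods),
              cfg$n_occasions, cfg$n_targets,
              if (is.null(cfg$n_raters)) 0 else unlist(cfg$n_raters))
}

#' Write a two-level dataset as delimited text
#'
#' Writes the target-level table, the rater-level table, and a YAML sidecar
#' recording the design, seed, package version, and a configuration hash.
#'
#' @param data An [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param name File-name stem.
#' @return Named vector of the written paths, invisibly.
#' @export
write_dataset <- function(data, dir, name = "dataset") {
  stopifnot(inherits(data, "lscom_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(targets = file.path(dir, paste0(name, "_targets.csv")),
             raters = file.path(dir, paste0(name, "_raters.csv")),
             meta = file.path(dir, paste0(name, "_meta.yml")))
  write.csv(data$target_table, paths["targets"], row.names = FALSE)
  write.csv(data$rater_table, paths["raters"], row.names = FALSE)
  dcfg <- design_to_config(data$design)
  yaml::write_yaml(c(list(design = dcfg),
                     provenance(seed = data$seed, config = dcfg)),
                   paths["meta"])
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the files.
#' @param name File-name stem.
#' @return An `lscom_dataset` (without the generating parameter set).
#' @export
read_dataset <- function(dir, name = "dataset") {
  meta_path <- file.path(dir, paste0(name, "_meta.yml"))
  if (!file.exists(meta_path)) {
    stop("no dataset sidecar at ", meta_path, call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  design <- design_from_config(meta$design)
  tt <- read.csv(file.path(dir, paste0(name, "_targets.csv")),
                 check.names = FALSE)
  rt <- read.csv(file.path(dir, paste0(name, "_raters.csv")),
                 check.names = FALSE)
  structure(list(target_table = tt, rater_table = rt, design = design,
                 seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
                 params = NULL),
            class = "lscom_dataset")
}

#' Write a fit report
#'
#' Produces a human-readable text report, a machine-readable key-value YAML
#' file, and the parameter table (label, estimate, SE, and true value when
#' known) as CSV.
#'
#' @param fit An [fit_ml()] result.
#' @param dir Output directory.
#' @param name File-name stem.
#' @param truth Optional named vector of true values to include.
#' @return Named vector of paths, invisibly.
#' @export
write_fit_report <- function(fit, dir, name = "fit", truth = NULL) {
  stopifnot(inherits(fit, "lscom_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(report = file.path(dir, paste0(name, "_report.txt")),
             values = file.path(dir, paste0(name, "_fit.yml")),
             params = file.path(dir, paste0(name, "_parameters.csv")))
  est <- fit$estimates
  if (!is.null(truth)) est$true <- unname(truth[est$label])
  write.csv(est, paths["params"], row.names = FALSE)
  yaml::write_yaml(c(list(
    logL = fit$logL, logL_saturated = fit$logL_saturated,
    chi_square = fit$chi_square, df = fit$df, p_value = fit$p_value,
    converged = fit$converged, iterations = fit$iterations,
    n_free = fit$n_free, n_targets = fit$n_targets,
    heywood = fit$heywood$flags), provenance()), paths["values"])
  con <- file(paths["report"], "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("lscom %s fit report", packageVersion("lscom")),
    sprintf("free parameters: %d", fit$n_free),
    sprintf("targets: %d", fit$n_targets),
    sprintf("log-likelihood: %.4f", fit$logL),
    sprintf("chi-square: %.4f on %d df (p = %.4f)",
            fit$chi_square, fit$df, fit$p_value),
    sprintf("converged: %s (%d iterations)", fit$converged, fit$iterations),
    sprintf("improper-solution flags: %s",
            paste(sprintf("%s=%s", names(fit$heywood$flags),
                          unlist(fit$heywood$flags)), collapse = ", "))),
    con)
  invisible(paths)
}

#' Read a run configuration file
#'
#' Configurations are YAML with sections `design`, `targets`, `constraints`,
#' `estimation`, `mc`, and `output`; unknown keys are rejected with the key
#' named.
#'
#' @param path YAML file path.
#' @return The configuration list (class `lscom_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no config file at ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("design", "targets", "constraints", "estimation", "mc", "output")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config section '", bad[1], "' (known: ",
         paste(known, collapse = ", "), ")", call. = FALSE)
  }
  structure(cfg, class = "lscom_config")
}

targets_from_config <- function(cfg) {
  tc <- cfg$targets
  if (is.null(tc) || is.null(tc$consistency)) {
    return(population_targets("low"))
  }
  if (tc$consistency %in% c("low", "high")) {
    population_targets(tc$consistency,
                       jitter = if (is.null(tc$jitter)) 0.025 else tc$jitter)
  } else {
    population_targets("custom", consistency_share = tc$consistency,
                       unique_ms = tc$unique_ms, common_ms = tc$common_ms,
                       struct_ms = tc$struct_ms, reliability = tc$reliability,
                       jitter = if (is.null(tc$jitter)) 0.025 else tc$jitter)
  }
}
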
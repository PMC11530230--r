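# Config-driven end-to-end orchestration with a reproducibility manifest.
# run_pipeline() is what the command-line wrapper (inst/cli/wfcm) calls; the
# R API (wfcm() and the stage functions) is the primary interface.

#' Default pipeline configuration
#'
#' @return a named list of all configuration keys with their defaults.
#' @export
default_config <- function() {
  list(input = character(), topology = NULL, chain_id = NULL,
       param_table = NULL, feature_kind = "omega",
       dim = 10L, seed = 0L, n_neighbors = 30L, min_dist = 0.1,
       min_cluster_fraction = 0.01, stride = 1L, first = 1L, last = Inf,
       outdir = "wfcm_out", n_samples = 10L)
}

#' Run the full characterization pipeline
#'
#' Executes load -> featurize -> embed -> partition -> characterize ->
#' report, writing a manifest (config echo, seeds, package version,
#' parameter-table digest) that allows an exact rerun. Any stage failure
#' aborts with a stage-named error.
#'
#' @param config a list of configuration keys; missing keys take the
#'   [default_config()] values. `input` (file paths) is required unless
#'   `ensemble` is given.
#' @param ensemble optionally, an already-loaded `ensemble` (skips the io
#'   stage).
#' @return the `wfcm` fit, invisibly; report files under `config$outdir`.
#' @export
run_pipeline <- function(config = list(), ensemble = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  stopifnot(cfg$min_cluster_fraction > 0, cfg$min_cluster_fraction < 1,
            cfg$dim >= 2L)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  if (is.null(ensemble)) {
    if (!length(cfg$input)) stop("config$input is required")
    ensemble <- stage("io", load_ensemble(cfg$input, topology = cfg$topology,
                                          chain = cfg$chain_id,
                                          stride = cfg$stride,
                                          first = cfg$first, last = cfg$last))
  }
  table <- NULL
  table_digest <- NA_character_
  if (cfg$feature_kind == "omega") {
    table <- stage("parameters", {
      if (is.null(cfg$param_table)) default_param_table()
      else read_param_table(cfg$param_table)
    })
    table_digest <- .table_digest(table)
  }
  fit <- stage("fit", wfcm(ensemble, table, feature_kind = cfg$feature_kind,
                           dim = cfg$dim, n_neighbors = cfg$n_neighbors,
                           min_dist = cfg$min_dist,
                           min_cluster_fraction = cfg$min_cluster_fraction,
                           seed = cfg$seed))
  stage("report", {
    if (!is.null(fit$characterization))
      write_report(fit$characterization, ensemble, fit$assignment,
                   cfg$outdir, n_samples = cfg$n_samples,
                   descriptors = fit$descriptors, seed = cfg$seed)
    else dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(config = cfg[setdiff(names(cfg), "last")],
                     last = if (is.finite(cfg$last)) cfg$last else NULL,
                     package_version = as.character(utils::packageVersion("wfcm")),
                     param_table_digest = table_digest,
                     n = ensemble$n, L = ensemble$L)
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })
  invisible(fit)
}

## Order-independent digest of a parameter table (sum of entry fingerprints)
.table_digest <- function(table) {
  v <- vapply(names(table$entries), function(k) {
    p <- table$entries[[k]]
    sum(utf8ToInt(k)) * 1e-3 + p$d_lo + 2 * p$d_hi +
      if (!is.null(p$q_pref)) sum(abs(p$q_pref)) else 0
  }, numeric(1L))
  sprintf("%.10e", sum(v))
}

#' Default bundled contact-parameter table
#'
#' The table shipped under `inst/extdata/`, estimated from the package's own
#' synthetic toy reference set. It makes the pipeline runnable out of the
#' box but is explicitly not publication grade: for real analyses
#' re-estimate from a curated collection of high-resolution structures with
#' [estimate_parameters()].
#'
#' @return a `contact_param_table`.
#' @export
default_param_table <- function() {
  path <- system.file("extdata", "contact_params_toy.json", package = "wfcm")
  if (!nzchar(path)) stop("bundled parameter table not found")
  read_param_table(path)
}
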
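#' Run a full simulation-to-evaluation benchmark
#'
#' Orchestrates the end-to-end pipeline: build (or load) a reference,
#' simulate every configured silver-standard dataset, compute every
#' configured feature selection on the reference, run every method on
#' every (dataset, strategy) cell, write each prediction as a proportions
#' TSV, and assemble a metric report with mean/sd aggregates.  Fully
#' reproducible from `(config, seed)`.
#'
#' The configuration is a list (or YAML file with the same structure):
#' \describe{
#'   \item{reference}{either `path:` to a dataset bundle
#'     ([read_dataset()]) or the arguments of [reference_config()].}
#'   \item{simulations}{named list; each entry is either the name of a
#'     [silver_presets()] entry or the arguments of
#'     [simulation_config()].}
#'   \item{strategies}{named list of
#'     `{strategy: highly_accessible|highly_variable_peaks|hvg_seurat,
#'     n_features: <int>}` (`n` is also accepted from R lists; in YAML a
#'     bare `n` key parses as a boolean).}
#'   \item{methods}{subset of `"majority_oracle"`,
#'     `"majority_global"`, `"nnls"`.}
#'   \item{rare_types, threshold}{optional [evaluate()] options.}
#' }
#'
#' @param config list or path to a YAML file.
#' @param seed integer master seed; all stage seeds derive from it.
#' @param out_dir output directory; proportion TSVs go to
#'   `out_dir/proportions/`, the row-level report to `report.tsv` and the
#'   aggregates to `report_summary.tsv`.
#' @return Invisibly, a list with `report`, `summary` and `paths`.
#' @export
run_benchmark <- function(config, seed = 1L, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validate_run_config(config)
  dir.create(file.path(out_dir, "proportions"), recursive = TRUE,
             showWarnings = FALSE)
  seeds <- derive_seeds(seed, 1L + length(config$simulations))

  reference <- if (!is.null(config$reference$path)) {
    read_dataset(config$reference$path)
  } else {
    generate_reference(do.call(reference_config, config$reference),
                       seed = seeds[1])
  }

  selections <- lapply(config$strategies, function(st) {
    switch(st$strategy,
      highly_accessible = select_highly_accessible(reference, n = st$n),
      highly_variable_peaks = select_highly_variable_peaks(reference,
                                                           n = st$n),
      hvg_seurat = select_hvg_seurat(reference, n = st$n),
      stop("unknown strategy '", st$strategy, "'"))
  })

  rows <- list()
  paths <- character(0)
  for (si in seq_along(config$simulations)) {
    sim_name <- names(config$simulations)[si]
    sim_cfg <- config$simulations[[si]]
    spots <- simulate_spots(reference, sim_cfg, seed = seeds[1 + si])
    truth <- true_proportions(spots)
    for (sti in seq_along(selections)) {
      st_name <- names(selections)[sti]
      sel <- selections[[sti]]
      for (meth in config$methods) {
        res <- tryCatch(
          .run_method(meth, reference, spots, sel, truth),
          error = function(e) {
            stop("benchmark cell (simulation=", sim_name, ", strategy=",
                 st_name, ", method=", meth, ") failed: ",
                 conditionMessage(e))
          })
        pfile <- file.path(out_dir, "proportions",
                           sprintf("%s__%s__%s.tsv", sim_name, st_name,
                                   meth))
        write_proportions(res$proportions, pfile)
        paths <- c(paths, pfile)
        row <- evaluate(truth, res$proportions,
                        rare_types = config$rare_types,
                        threshold = config$threshold,
                        method = meth, modality = sel$modality,
                        strategy = sel$strategy)
        row <- cbind(data.frame(simulation = sim_name), row)
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  report <- do.call(rbind, rows)
  summary <- aggregate_report(report)
  rpath <- file.path(out_dir, "report.tsv")
  spath <- file.path(out_dir, "report_summary.tsv")
  for (x in list(list(report, rpath), list(summary, spath))) {
    atomic_write(function(tmp) {
      write.table(x[[1]], tmp, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }, x[[2]])
  }
  invisible(list(report = report, summary = summary,
                 paths = c(paths, rpath, spath)))
}

.run_method <- function(method, reference, spots, sel, truth) {
  switch(method,
    majority_oracle = majority_baseline(truth, "oracle_spot"),
    majority_global = majority_baseline(truth, "global_reference",
                                        reference_labels =
                                          cell_types(reference)),
    nnls = nnls_deconvolve(reference, spots, selection = sel),
    stop("unknown method '", method, "'"))
}

# Fail-fast validation: every block must resolve before any stage runs.
.validate_run_config <- function(config) {
  if (is.null(config$reference)) stop("config needs a 'reference' block")
  if (!is.null(config$reference$path) &&
      !dir.exists(config$reference$path)) {
    stop("reference path does not exist: ", config$reference$path)
  }
  if (is.null(config$simulations) || !length(config$simulations)) {
    stop("config needs at least one simulation")
  }
  presets <- silver_presets()
  config$simulations <- lapply(config$simulations, function(s) {
    if (inherits(s, "simulation_config")) return(s)
    if (is.character(s) && length(s) == 1) {
      if (!s %in% names(presets)) {
        stop("unknown simulation preset '", s, "'")
      }
      return(presets[[s]])
    }
    do.call(simulation_config, s)
  })
  if (is.null(names(config$simulations)) ||
      any(names(config$simulations) == "")) {
    names(config$simulations) <-
      paste0("sim", seq_along(config$simulations))
  }
  if (is.null(config$strategies) || !length(config$strategies)) {
    stop("config needs at least one feature-selection strategy")
  }
  config$strategies <- lapply(config$strategies, function(st) {
    if (is.null(st$strategy)) stop("each strategy needs a 'strategy' name")
    # accept 'n_features' as well: a bare 'n' key is a YAML 1.1 boolean
    if (is.null(st$n)) st$n <- st$n_features
    if (is.null(st$n)) stop("each strategy needs 'n' (or 'n_features')")
    st
  })
  if (is.null(names(config$strategies)) ||
      any(names(config$strategies) == "")) {
    names(config$strategies) <-
      vapply(config$strategies, `[[`, "", "strategy")
  }
  if (is.null(config$methods)) config$methods <- c("majority_oracle")
  bad <- setdiff(config$methods,
                 c("majority_oracle", "majority_global", "nnls"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (is.null(config$threshold)) config$threshold <- 0.05
  config
}
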
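#' Read and validate a pipeline configuration
#'
#' Configuration is JSON or YAML with nested sections `preprocess`
#' (keys of [preprocess_config()]), `deconvolve` (`window`, `rate`,
#' `types`), `kernels` (`family`, `set`), `stats` (`alpha_cluster`,
#' `n_perm`), plus top-level `seed` and `log_level`. Unknown keys are
#' rejected so typos cannot silently change an analysis.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file, or a named
#'   list already in memory.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list()
    else if (is.list(path)) path
    else if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)

  known <- list(
    preprocess = names(formals(preprocess_config)),
    deconvolve = c("window", "rate", "types"),
    kernels = c("family", "set", "support"),
    stats = c("alpha_cluster", "n_perm"),
    seed = NULL, log_level = NULL)
  bad <- setdiff(names(cfg), names(known))
  if (length(bad))
    stop("pipeline_config: unknown section(s): ", paste(bad, collapse = ", "))
  for (sec in intersect(names(cfg), c("preprocess", "deconvolve",
                                      "kernels", "stats"))) {
    bad <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(bad))
      stop("pipeline_config: unknown key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  pp <- do.call(preprocess_config, cfg$preprocess %||% list())
  dv <- utils::modifyList(
    list(window = c(-0.5, 5), rate = 10,
         types = c("sound_high", "sound_low", "blink", "saccade")),
    cfg$deconvolve %||% list())
  if (dv$window[1] >= dv$window[2])
    stop("pipeline_config: deconvolve window start must precede its end ",
         "(keys deconvolve.window)")
  kn <- utils::modifyList(list(family = "gamma", set = "table1", support = 6),
                          cfg$kernels %||% list())
  st <- utils::modifyList(list(alpha_cluster = 0.05, n_perm = 1000),
                          cfg$stats %||% list())
  structure(list(preprocess = pp, deconvolve = dv, kernels = kn, stats = st,
                 seed = as.integer(cfg$seed %||% 1L),
                 log_level = cfg$log_level %||% "info"),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Fixed stage order on one recording: read inputs, interpolate blinks,
#' band-pass (phasic) and low-pass (tonic), normalize, resample, FIR
#' deconvolution of all event types jointly, kernel post-processing,
#' parametric kernel fits, and delimited-text / JSON outputs plus a
#' machine-readable report (parameters, seed, per-file checksums). Any
#' stage failure aborts with the stage name and the underlying message.
#'
#' @param config a [pipeline_config()] (or path passed to it).
#' @param samples_path,events_path input TSV paths ([read_samples()],
#'   [read_events()]); alternatively pass `session` (a `pupil_session`
#'   from [simulate_session()]).
#' @param out_dir output directory, created if needed.
#' @param session optional `pupil_session` replacing the file inputs.
#' @param normalize passed to [preprocess_pupil()]; simulator sessions
#'   are generated in z-units and skip normalization by default.
#' @return (invisibly) the report list; files are written to `out_dir`.
#' @export
run_pipeline <- function(config, samples_path = NULL, events_path = NULL,
                         out_dir, session = NULL,
                         normalize = is.null(session)) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- stage("read", {
    if (!is.null(session)) {
      list(ts = session$raw, events = session$truth$events)
    } else {
      list(ts = read_samples(samples_path), events = read_events(events_path))
    }
  })
  blinks <- events_of_type(inputs$events, "blink")
  pre <- stage("preprocess",
               preprocess_pupil(inputs$ts, blinks, config$preprocess,
                                normalize = normalize))
  fit <- stage("deconvolve", {
    types <- intersect(config$deconvolve$types, unique(inputs$events$type))
    d <- build_design_matrix(inputs$events,
                             n_samples = length(pre$phasic$samples),
                             rate = config$deconvolve$rate,
                             window = config$deconvolve$window,
                             event_types = types)
    postprocess_kernels(fir_deconv(d, pre$phasic),
                        baseline_window = c(config$deconvolve$window[1], 0))
  })
  fits <- stage("fit_kernels", {
    out <- list()
    for (tp in fit$event_types) {
      fam <- if (tp == "blink") "double_gamma" else config$kernels$family
      out[[tp]] <- fit_kernel(fit$lags, fit$kernels[, tp], family = fam)
    }
    out
  })
  vp <- stage("variance_partition", variance_partition(fit))

  paths <- list(phasic = file.path(out_dir, "phasic.tsv"),
                tonic = file.path(out_dir, "tonic.tsv"),
                kernels = file.path(out_dir, "kernels.tsv"),
                params = file.path(out_dir, "kernel_params.json"),
                report = file.path(out_dir, "report.json"))
  stage("write", {
    write_samples(pre$phasic, paths$phasic)
    write_samples(pre$tonic, paths$tonic)
    write_kernels(fit, paths$kernels)
    params <- lapply(fits, function(f)
      c(list(family = f$family, rms = f$rms,
             time_to_peak = time_to_peak(f$kernel)),
        as.list(coef(f))))
    jsonlite::write_json(params, paths$params, auto_unbox = TRUE, digits = NA)
  })

  report <- list(
    seed = config$seed,
    parameters = list(preprocess = unclass(config$preprocess),
                      deconvolve = config$deconvolve,
                      kernels = config$kernels),
    n_events = as.list(table(inputs$events$type)),
    r_squared = fit$r_squared,
    variance_fractions = as.list(vp$fractions),
    checksums = {
      files <- unlist(paths[c("phasic", "tonic", "kernels", "params")])
      as.list(stats::setNames(unname(tools::md5sum(files)), names(files)))
    })
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
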
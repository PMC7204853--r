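# End-to-end pipeline: extract -> build-pairs -> fit, with a YAML
# configuration, per-stage output files and a run manifest.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Window
#' defaults are the case-crossover definitions (case 1-30, control 61-90 days
#' prior to the index admission).
#'
#' @param documents,admissions,appointments,stays Input file paths (formats
#'   as in [read_documents()] and [read_admissions()]).
#' @param out_dir Directory for stage outputs.
#' @param exposure `"binary"` or `"per_token"`.
#' @param covariates Character vector of adjustment variables among
#'   `face_to_face`, `dna`, `bed_days` (empty = unadjusted).
#' @param case_window,control_window Integer pairs of days prior, boundaries
#'   inclusive.
#' @param study_start,study_end Optional bounds on index admission dates.
#' @param max_quote_chars Runaway-quote cap for the extractor.
#'
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(documents, admissions, appointments, stays,
                            out_dir, exposure = "binary",
                            covariates = character(),
                            case_window = c(1L, 30L),
                            control_window = c(61L, 90L),
                            study_start = NULL, study_end = NULL,
                            max_quote_chars = 1500L) {
  exposure <- match.arg(exposure, c("binary", "per_token"))
  stopifnot(all(covariates %in% c("face_to_face", "dna", "bed_days")))
  cfg <- list(documents = documents, admissions = admissions,
              appointments = appointments, stays = stays, out_dir = out_dir,
              exposure = exposure, covariates = covariates,
              case_window = as.integer(case_window),
              control_window = as.integer(control_window),
              study_start = study_start, study_end = study_end,
              max_quote_chars = as.integer(max_quote_chars))
  # reuse the window validation in assign_window
  assign_window(Sys.Date(), Sys.Date(), cfg$case_window, cfg$control_window)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments;
#'   relative input paths are resolved against the file's directory.
#'
#' @return Object of class `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  pipeline_config(
    documents = resolve(y$documents), admissions = resolve(y$admissions),
    appointments = resolve(y$appointments), stays = resolve(y$stays),
    out_dir = resolve(y$out_dir %||% "."),
    exposure = y$exposure %||% "binary",
    covariates = as.character(y$covariates %||% character()),
    case_window = as.integer(y$case_window %||% c(1L, 30L)),
    control_window = as.integer(y$control_window %||% c(61L, 90L)),
    study_start = y$study_start, study_end = y$study_end,
    max_quote_chars = y$max_quote_chars %||% 1500L)
}

#' Run the full extract / build-pairs / fit pipeline
#'
#' Reads the input files, extracts quoted spans, builds the matched-pair
#' table, fits the conditional logistic model, and writes `spans.jsonl`,
#' `pairs.csv`, `fit.json`, `audit.json` and `manifest.json` to
#' `config$out_dir`. Any stage failure halts with the stage name.
#'
#' @param config A [pipeline_config()], or the path to a YAML file for
#'   [load_pipeline_config()].
#'
#' @return Invisibly, a list with the `clr_fit` object, the pair table, the
#'   exclusion audit and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("documents", "admissions", "appointments", "stays")) {
    if (!file.exists(config[[f]])) {
      stop(sprintf("stage input: %s file not found: %s", f, config[[f]]))
    }
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  ecfg <- extraction_config(max_quote_chars = config$max_quote_chars)

  docs <- stage("read", read_documents(config$documents))
  adm <- stage("read", read_admissions(config$admissions))
  app <- stage("read", read_appointments(config$appointments))
  sty <- stage("read", read_stays(config$stays))

  spans <- stage("extract", extract_corpus(docs, ecfg))
  write_spans(spans, file.path(config$out_dir, "spans.jsonl"))

  pairs <- stage("build-pairs", build_matched_pairs(
    docs, adm, app, sty, spans = spans, cfg = ecfg,
    case_window = config$case_window, control_window = config$control_window,
    study_start = config$study_start, study_end = config$study_end))
  write_pairs(pairs, file.path(config$out_dir, "pairs.csv"))
  audit <- attr(pairs, "audit")
  jsonlite::write_json(audit, file.path(config$out_dir, "audit.json"),
                       auto_unbox = TRUE, digits = NA)

  fit <- stage("fit", clr_fit(pairs, exposure = config$exposure,
                              covariates = config$covariates))
  report <- list(exposure = config$exposure, covariates = config$covariates,
                 coefficients = as.list(fit$coefficients),
                 standard_errors = as.list(fit$standard_errors),
                 odds_ratios = as.list(fit$odds_ratios),
                 ci_low = as.list(fit$ci_low), ci_high = as.list(fit$ci_high),
                 p_values = as.list(fit$p_values),
                 log_likelihood = fit$log_likelihood,
                 n_pairs = fit$n_pairs,
                 n_informative_pairs = fit$n_informative_pairs,
                 converged = fit$converged, iterations = fit$iterations)
  jsonlite::write_json(report, file.path(config$out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_plain <- unclass(config)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(config = cfg_plain,
                   config_md5 = unname(tools::md5sum(tmp)),
                   package_version = as.character(utils::packageVersion("quotecross")),
                   r_version = as.character(getRversion()),
                   n_documents = nrow(docs), n_spans = nrow(spans),
                   audit = audit)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(fit = fit, pairs = pairs, audit = audit,
                 manifest = manifest))
}
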
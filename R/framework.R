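#' Counter-based substream seeds
#'
#' Derives a deterministic per-(stage, subject, run) seed from a master
#' seed so that independent pipeline stages and subjects get independent,
#' stable random streams: adding subjects or stages never perturbs the
#' streams already in use.
#'
#' @param master Master integer seed.
#' @param stage Stage label (any string).
#' @param subject,run Optional integer counters.
#' @return A positive integer seed below 2^31.
#' @export
substream_seed <- function(master, stage, subject = 0L, run = 0L) {
  m <- 2147483647          # 2^31 - 1, Mersenne prime
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  s <- (as.numeric(master) %% m) * 48271 %% m
  s <- (s + h * 16807) %% m
  s <- (s + as.numeric(subject) * 69621) %% m
  s <- (s + as.numeric(run) * 40692) %% m
  as.integer(s %% (m - 1) + 1)
}

trial_columns <- c("session_id", "subject_id", "run", "trial", "phase",
                   "stimulus_id", "category", "condition", "chunk_id",
                   "repetition", "iti_ms")
response_columns <- c(trial_columns, "rt_s", "correct")
numeric_trial_cols <- c("run", "trial", "repetition", "iti_ms", "rt_s",
                        "nvar")

#' Read and write trial tables
#'
#' Trial and response tables are stored as plain UTF-8 CSV with a header
#' row and `.` as the decimal separator, one row per trial, columns
#' `session_id, subject_id, run, trial, phase, stimulus_id, category,
#' condition, chunk_id, repetition, iti_ms` plus, when present, `rt_s`,
#' `correct` and `nvar`.  `write_trials()` followed by `read_trials()` is
#' the identity on all schema columns; malformed numeric fields (including
#' decimal commas) raise a parse error naming the row.
#'
#' @param trials A trial or response data frame.
#' @param path File path.
#' @return `read_trials()` returns the validated data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing)) {
    stop("trial table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8", na.strings = ""),
    error = function(e) {
      stop("cannot parse ", path, " as a trial CSV: ",
           conditionMessage(e), call. = FALSE)
    })
  missing <- setdiff(trial_columns, names(raw))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- raw
  for (col in intersect(numeric_trial_cols, names(raw))) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      hint <- if (any(grepl(",", v[bad]))) {
        " (decimal commas are not accepted; use '.')"
      } else ""
      stop("malformed numeric value ", dQuote(v[bad[1]]), " in column '",
           col, "', row ", bad[1], hint)
    }
    out[[col]] <- if (col %in% c("run", "trial", "repetition", "nvar")) {
      as.integer(num)
    } else num
  }
  if ("correct" %in% names(raw)) {
    v <- toupper(raw$correct)
    ok <- is.na(v) | v %in% c("TRUE", "FALSE")
    if (!all(ok)) {
      stop("malformed logical value in column 'correct', row ",
           which(!ok)[1])
    }
    out$correct <- as.logical(v)
  }
  out
}

default_pipeline_config <- function() {
  list(preset = "exp1b", subjects = 5L, seed = 1L,
       observer = list(), filter = list(),
       stats = "group", out_dir = "slonline_out")
}

#' Run the end-to-end pipeline
#'
#' Chains design generation, response simulation, preprocessing and the
#' requested inference stage, writing CSV/JSON artifacts and a run
#' manifest (config snapshot, seeds, package version, per-artifact MD5
#' hashes, timestamps) into `out_dir`.  Re-running with the same config
#' and seed reproduces byte-identical CSV/JSON stage outputs.
#'
#' @param config A configuration list (or path to a YAML file) with fields
#'   `preset` (`"exp1a"`, `"exp1b"`, `"exp2"`), `subjects`, `seed`,
#'   optional `design` (overrides for [design_spec()]), `observer`
#'   (arguments for [observer_params()]), `filter` (arguments for
#'   [filter_config()]), `stats` (`"group"`, `"trajectory"` or `"none"`)
#'   and `out_dir`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "slonline",
                   version = as.character(utils::packageVersion("slonline")),
                   config = cfg, started = format(Sys.time(), usetz = TRUE),
                   stages = list())
  paths <- character(0)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(res))
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok", artifacts = res)
    res
  }

  spec <- do.call(design_spec, c(list(preset = cfg$preset),
                                 cfg$design %||% list()))
  params <- do.call(observer_params, cfg$observer %||% list())
  fconf <- do.call(filter_config, cfg$filter %||% list())

  responses <- NULL
  run_stage("simulate", function() {
    responses <<- make_cohort(spec, cfg$subjects, params, seed = cfg$seed)
    p <- file.path(cfg$out_dir, "responses.csv")
    write_trials(responses, p)
    paths <<- c(paths, p)
    basename(p)
  })

  pre <- NULL
  run_stage("preprocess", function() {
    pre <<- preprocess(responses, fconf)
    p1 <- file.path(cfg$out_dir, "preprocessed.csv")
    write_trials(pre$data, p1)
    p2 <- file.path(cfg$out_dir, "exclusion_report.json")
    jsonlite::write_json(unclass(pre$report), p2, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    paths <<- c(paths, p1, p2)
    basename(c(p1, p2))
  })

  if (identical(cfg$stats, "group")) {
    run_stage("stats", function() {
      summ <- summarize_conditions(pre$data)
      res <- list(rm_anova = unclass(rm_anova_rt(summ)),
                  friedman = unclass(friedman_accuracy(summ)))
      p <- file.path(cfg$out_dir, "group_stats.json")
      jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
      paths <<- c(paths, p)
      basename(p)
    })
  } else if (identical(cfg$stats, "trajectory")) {
    run_stage("stats", function() {
      fit <- fit_rt_trajectory(pre$data)
      comp <- sp2_encompassing(pre$data)
      res <- list(
        anova = as.data.frame(fit$anova),
        emm = fit$emm, trends = fit$trends,
        trend_contrasts = fit$trend_contrasts,
        encompassing = comp[c("r2_linear", "r2_log", "r2_combined",
                              "f_linear_vs_combined", "p_linear_vs_combined",
                              "f_log_vs_combined", "p_log_vs_combined",
                              "verdict")])
      p <- file.path(cfg$out_dir, "trajectory_stats.json")
      jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
      paths <<- c(paths, p)
      basename(p)
    })
  }

  manifest$hashes <- as.list(unname(tools::md5sum(paths)))
  names(manifest$hashes) <- basename(paths)
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
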
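## Dataset validation, readers/writers and run logging. The study-level
## table has one row per experimental arm; each row must provide its
## effect size in exactly one of three forms, resolved in this order:
## an explicit sampling variance `var`, a confidence interval
## `ci_low`/`ci_high`, or arm-level summaries
## `mean_t, sd_t, n_t, mean_c, sd_c, n_c`.

.norm_rating <- function(x) {
  y <- tolower(trimws(as.character(x)))
  y[y %in% c("", "na", "n/a", "not assessed", "notassessed", "not_assessed")] <-
    "not_assessed"
  y[is.na(x)] <- "not_assessed"
  y
}

#' Read and validate a meta-epidemiological dataset
#'
#' Accepts file paths to delimited text (header row required, comma
#' default) or in-memory data frames. Violations are collected -- not
#' fail-fast -- into a structured report (`row`, `column`, `rule`,
#' `message`); rows whose effect size cannot be resolved are dropped
#' and reported. Rating columns are case-normalized (`"Low"` ->
#' `"low"`), with normalizations logged.
#'
#' @param studies Path or data frame of arm-level rows: `ma_id`,
#'   `study_id`, `arm_id`, effect-size columns as above, and one
#'   `rob_*` column per assessed characteristic.
#' @param mas Path or data frame of meta-analysis rows: `ma_id`,
#'   `expected_direction` (`benefit_positive`/`benefit_negative`/
#'   `unclear`), optionally `design`.
#' @param sep Field separator for file input.
#' @param bias_corrected Passed to [compute_smd()] when effect sizes
#'   are resolved from arm summaries.
#'
#' @return A `"metaepi_dataset"` whose `provenance` element carries the
#'   source paths and the validation report; `provenance$valid` is
#'   `TRUE` when the report is empty.
#' @export
validate_dataset <- function(studies, mas, sep = ",", bias_corrected = TRUE) {
  src <- c(studies = if (is.character(studies)) studies else "<data.frame>",
           mas = if (is.character(mas)) mas else "<data.frame>")
  if (is.character(studies)) {
    studies <- utils::read.table(studies, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE, quote = "\"")
  }
  if (is.character(mas)) {
    mas <- utils::read.table(mas, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, quote = "\"")
  }
  report <- list()
  note <- function(row, column, rule, message) {
    report[[length(report) + 1]] <<- data.frame(
      row = row, column = column, rule = rule, message = message)
  }
  for (col in c("ma_id", "study_id", "arm_id")) {
    if (!col %in% names(studies)) {
      stop("studies table lacks required column: ", col)
    }
  }
  if (!all(c("ma_id", "expected_direction") %in% names(mas))) {
    stop("mas table lacks ma_id/expected_direction")
  }

  key <- paste(studies$ma_id, studies$study_id, studies$arm_id)
  for (i in which(duplicated(key))) {
    note(i, "arm_id", "unique_key", "duplicate (ma_id, study_id, arm_id)")
  }
  for (i in which(!studies$ma_id %in% mas$ma_id)) {
    note(i, "ma_id", "orphan_ma", "ma_id absent from mas table")
  }
  bad_dir <- !mas$expected_direction %in%
    c("benefit_positive", "benefit_negative", "unclear")
  for (i in which(bad_dir)) {
    note(i, "expected_direction", "direction_value",
         paste("invalid direction:", mas$expected_direction[i]))
  }

  has <- function(cols) all(cols %in% names(studies))
  n <- nrow(studies)
  smd <- if ("smd" %in% names(studies)) studies$smd else rep(NA_real_, n)
  var <- if ("var" %in% names(studies)) studies$var else rep(NA_real_, n)
  drop <- logical(n)
  for (i in seq_len(n)) {
    if (!is.na(var[i])) {
      if (has(c("ci_low", "ci_high")) &&
          !is.na(studies$ci_low[i]) && !is.na(studies$ci_high[i])) {
        note(i, "var", "precedence", "both var and CI given; CI ignored")
      }
      if (is.na(smd[i])) {
        note(i, "smd", "missing_smd", "var given without smd")
        drop[i] <- TRUE
      }
    } else if (has(c("ci_low", "ci_high")) &&
               !is.na(studies$ci_low[i]) && !is.na(studies$ci_high[i])) {
      es <- tryCatch(smd_from_ci(smd[i], studies$ci_low[i], studies$ci_high[i]),
                     error = function(e) e)
      if (inherits(es, "error")) {
        note(i, "ci_low", "ci_resolution", conditionMessage(es))
        drop[i] <- TRUE
      } else {
        var[i] <- es$variance
      }
    } else if (has(c("mean_t", "sd_t", "n_t", "mean_c", "sd_c", "n_c")) &&
               !is.na(studies$mean_t[i])) {
      es <- tryCatch(
        compute_smd(studies$mean_t[i], studies$sd_t[i], studies$n_t[i],
                    studies$mean_c[i], studies$sd_c[i], studies$n_c[i],
                    bias_corrected = bias_corrected),
        error = function(e) e)
      if (inherits(es, "error")) {
        note(i, "mean_t", "summary_resolution", conditionMessage(es))
        drop[i] <- TRUE
      } else {
        smd[i] <- es$smd
        var[i] <- es$variance
      }
    } else {
      note(i, "var", "unresolvable_effect",
           "no variance, confidence interval, or arm summaries")
      drop[i] <- TRUE
    }
    if (!drop[i] && (is.na(var[i]) || var[i] <= 0)) {
      note(i, "var", "nonpositive_variance", "resolved variance not > 0")
      drop[i] <- TRUE
    }
  }
  studies$smd <- smd
  studies$var <- var

  rob_cols <- intersect(paste0("rob_", rob_characteristics), names(studies))
  for (col in rob_cols) {
    raw <- as.character(studies[[col]])
    normed <- .norm_rating(raw)
    changed <- which(!is.na(raw) & raw != normed)
    for (i in changed) {
      note(i, col, "rating_normalized",
           paste0("'", raw[i], "' normalized to '", normed[i], "'"))
    }
    bad <- which(!normed %in% .rating_levels)
    for (i in bad) {
      note(i, col, "rating_value", paste("invalid rating:", normed[i]))
      normed[i] <- "not_assessed"
    }
    studies[[col]] <- normed
  }

  report <- if (length(report)) do.call(rbind, report) else
    data.frame(row = integer(0), column = character(0),
               rule = character(0), message = character(0))
  out <- list(studies = studies[!drop, , drop = FALSE], mas = mas,
              provenance = list(
                sources = src, schema_version = "1.0", report = report,
                valid = !nrow(report), n_dropped = sum(drop)))
  class(out) <- "metaepi_dataset"
  out
}

#' Write pipeline results to a deterministic file set
#'
#' Writes `metaepi_results.csv` (one row per characteristic, including
#' skipped ones with their reason), `dmsd_per_ma.csv` (step-1 DMSD
#' estimates of every contributing meta-analysis) and `run_log.json`
#' (config echo, seed, exclusion log with machine-readable reasons,
#' package version). Byte-identical across runs with identical inputs
#' and config.
#'
#' @param results A `"metaepi_results"` object from [run_all()].
#' @param out_dir Output directory (created if needed).
#' @param config The [run_config()] used (echoed into the log).
#'
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir, config = run_config()) {
  stopifnot(inherits(results, "metaepi_results"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir,
                     c("metaepi_results.csv", "dmsd_per_ma.csv", "run_log.json"))
  utils::write.csv(as.data.frame(results), paths[1], row.names = FALSE)
  per_ma <- do.call(rbind, lapply(results, function(r) {
    if (r$skipped || nrow(r$per_ma) == 0) return(NULL)
    cbind(characteristic = r$characteristic, r$per_ma)
  }))
  if (is.null(per_ma)) {
    per_ma <- data.frame(characteristic = character(0), ma_id = character(0),
                         dmsd = numeric(0), se = numeric(0))
  }
  utils::write.csv(per_ma, paths[2], row.names = FALSE)
  exclusions <- do.call(rbind, lapply(results, function(r) {
    if (nrow(r$exclusions) == 0) return(NULL)
    cbind(characteristic = r$characteristic, r$exclusions)
  }))
  log <- list(package_version = as.character(utils::packageVersion("metaepi")),
              config = unclass(config),
              seed = config$seed,
              exclusions = if (is.null(exclusions)) list() else exclusions)
  jsonlite::write_json(log, paths[3], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Write a simulated dataset as CSV + JSON truth record
#'
#' @param dataset A `metaepi_dataset` from [simulate_dataset()].
#' @param out_dir Output directory.
#' @return Invisibly, the paths written (`studies.csv`, `mas.csv`,
#'   `truth.json`).
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("studies.csv", "mas.csv", "truth.json"))
  utils::write.csv(dataset$studies, paths[1], row.names = FALSE)
  utils::write.csv(dataset$mas, paths[2], row.names = FALSE)
  if (!is.null(dataset$truth)) {
    truth <- dataset$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(paths)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unset keys keep their [run_config()] defaults.
#'
#' @param path YAML file whose top-level keys match [run_config()]
#'   arguments.
#' @return A `"metaepi_config"`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
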
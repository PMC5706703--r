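#' Write a trial table to CSV
#'
#' Positions are stored in screen-width units at 12 significant digits, so
#' a write-then-read round trip is lossless for practical purposes.
#' Missing responses (timeouts) are written as empty fields.
#'
#' @param trials Trial data frame (see [simulate_subject()] for columns).
#' @param path Output CSV path.
#' @param manifest_path Optional path for the cohort manifest JSON (the
#'   observers' ground-truth parameters, written only when `trials`
#'   carries a `"manifest"` attribute).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, manifest_path = NULL) {
  out <- as.data.frame(trials)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "", formatC(x, digits = 12, format = "g"))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  man <- attr(trials, "manifest")
  if (!is.null(manifest_path) && !is.null(man))
    jsonlite::write_json(man, manifest_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads per-trial estimation data into the package's trial layout.
#' Deposited data sets with different column names are adapted through
#' `column_map`, a named character vector mapping canonical names to the
#' file's names (e.g. `c(response = "estimate")`). Blank or `NA` entries
#' in `response` are kept as missing (timeouts); `caught` is recomputed
#' from the responses when absent.
#'
#' @param path CSV file with a header row.
#' @param column_map Optional named character vector: names are canonical
#'   column names, values the file's column names.
#' @param design [task_design()] used to validate conditions and, when
#'   `caught` is absent, recompute it.
#' @return A trial data frame with attribute `"design"`.
#' @export
read_trials <- function(path, column_map = NULL, design = task_design()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop("column_map source column not in file: ", src, call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  mandatory <- c("subject_id", "block", "trial_index", "prior_sd",
                 "likelihood_sd", "target", "net_init", "response")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("trial CSV lacks mandatory columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  splash_cols <- grep("^splash_[0-9]+$", names(raw), value = TRUE)
  if (length(splash_cols) != design$n_samples)
    stop("expected ", design$n_samples, " splash_* columns, found ",
         length(splash_cols), call. = FALSE)
  numc <- c("block", "trial_index", "prior_sd", "likelihood_sd", "target",
            splash_cols, "net_init", "response",
            intersect(c("age"), names(raw)))
  for (cc in numc) {
    v <- raw[[cc]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
      bad <- which(!is.na(v) & v != "" & is.na(v2))
      if (length(bad) && cc != "response")
        stop("unparseable numeric in column '", cc, "' at data row(s): ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      raw[[cc]] <- v2
    }
  }
  must_finite <- c("target", splash_cols, "net_init")
  for (cc in must_finite)
    if (anyNA(raw[[cc]]))
      stop("missing values in mandatory column '", cc, "' at row(s): ",
           paste(utils::head(which(is.na(raw[[cc]])), 5), collapse = ", "),
           call. = FALSE)
  dup <- duplicated(raw[, c("subject_id", "block", "trial_index")])
  if (any(dup))
    stop("duplicate (subject, block, trial_index) at data row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  if ("caught" %in% names(raw)) {
    if (!is.logical(raw$caught))
      raw$caught <- as.logical(ifelse(raw$caught == "", NA, raw$caught))
  } else {
    raw$caught <- ifelse(is.na(raw$response), NA,
                         abs(raw$response - raw$target) <=
                           design$net_halfwidth)
  }
  attr(raw, "design") <- design
  raw
}

#' Write slope and performance tables
#'
#' Emits the tidy per-subject-per-condition slopes CSV and the per-subject
#' performance CSV from a fitted model.
#'
#' @param fit An [estimation_fit()].
#' @param slopes_path,performance_path Output CSV paths (`NULL` to skip).
#' @return The fit, invisibly.
#' @export
write_fit <- function(fit, slopes_path = NULL, performance_path = NULL) {
  stopifnot(inherits(fit, "estimation_fit"))
  if (!is.null(slopes_path))
    utils::write.csv(fit$slopes, slopes_path, row.names = FALSE, na = "")
  if (!is.null(performance_path))
    utils::write.csv(fit$performance, performance_path, row.names = FALSE,
                     na = "")
  invisible(fit)
}

#' Read a pipeline configuration from JSON
#'
#' The configuration holds the task-design fields, the cohort
#' specification, analysis options and the output directory. Unknown keys
#' are rejected so that typos fail loudly.
#'
#' @param path JSON file.
#' @return A list of class `run_config` with elements `design`
#'   (a [task_design()]), `cohort`, `analysis` and `out_dir`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("design", "cohort", "analysis", "out_dir", "trials_csv",
             "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         "\n  known keys: ", paste(known, collapse = ", "), call. = FALSE)
  design_args <- cfg$design
  if (!is.null(design_args)) {
    bad <- setdiff(names(design_args), names(formals(task_design)))
    if (length(bad))
      stop("unknown design keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (!is.null(design_args$prior_sds))
      design_args$prior_sds <- unlist(design_args$prior_sds)
    if (!is.null(design_args$likelihood_sds))
      design_args$likelihood_sds <- unlist(design_args$likelihood_sds)
  }
  design <- do.call(task_design, as.list(design_args))
  cohort <- cfg$cohort
  if (!is.null(cohort)) {
    bad <- setdiff(names(cohort),
                   c("n_per_group", "cp_spec", "td_spec", "age_mean",
                     "age_sd"))
    if (length(bad))
      stop("unknown cohort keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (nm in c("cp_spec", "td_spec"))
      if (!is.null(cohort[[nm]]))
        cohort[[nm]] <- do.call(group_spec, as.list(cohort[[nm]]))
  }
  analysis <- cfg$analysis
  if (!is.null(analysis)) {
    bad <- setdiff(names(analysis),
                   c("n_boot", "conf", "intercept", "screen_filter",
                     "chance", "paired", "alternative"))
    if (length(bad))
      stop("unknown analysis keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(list(design = design,
                 cohort = cohort,
                 analysis = analysis,
                 out_dir = cfg$out_dir,
                 trials_csv = cfg$trials_csv,
                 seed = cfg$seed),
            class = "run_config")
}
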
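#' Read a trajectory from delimited text
#'
#' Expects a tab- or comma-separated file with header columns `time_s`,
#' `extension_nm` and `force_pN`. Metadata, including the constant trap
#' separation, may be carried in leading comment lines of the form
#' `# key: value`. A legacy two-column file (time, extension) is accepted
#' with a warning when the force is recorded in the metadata instead.
#'
#' @param path File path.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, n = 100L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    if (grepl(":", kv)) {
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  df <- readr::read_delim(
    path, delim = "\t", comment = "#", show_col_types = FALSE,
    progress = FALSE
  )
  if (ncol(df) == 1L) { # not tab-separated; retry as csv
    df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  }
  if (!all(c("time_s", "extension_nm") %in% names(df))) {
    stop("'", path, "': missing required columns time_s/extension_nm",
         call. = FALSE)
  }
  force <- df[["force_pN"]]
  if (is.null(force)) {
    warning("'", path, "': no force_pN column; using metadata force if any",
            call. = FALSE)
    force <- rep(
      if (!is.null(meta$force_pN)) meta$force_pN else NA_real_,
      nrow(df)
    )
  }
  sep <- if (!is.null(meta$trap_separation_nm)) meta$trap_separation_nm else NA_real_
  trajectory(df$time_s, df$extension_nm, force,
             trap_separation_nm = sep, metadata = meta)
}

#' Write a trajectory to tab-separated text
#'
#' The trap separation and any scalar metadata are written as `# key: value`
#' comment lines before the header, so [read_trajectory()] round-trips
#' losslessly.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  sep <- attr(traj, "trap_separation_nm")
  if (is.finite(sep)) {
    writeLines(sprintf("# trap_separation_nm: %.10g", sep), con)
  }
  meta <- attr(traj, "metadata")
  for (key in names(meta)) {
    v <- meta[[key]]
    if (is.atomic(v) && length(v) == 1L && key != "trap_separation_nm") {
      writeLines(sprintf("# %s: %s", key, format(v, digits = 15)), con)
    }
  }
  writeLines(paste(c("time_s", "extension_nm", "force_pN"), collapse = "\t"), con)
  body <- sprintf("%.9g\t%.9g\t%.9g",
                  traj$time_s, traj$extension_nm, traj$force_pN)
  writeLines(body, con)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML document holding physical constants, construct/state definitions and
#' analysis options. Values must be positive where physical; unknown
#' top-level keys are rejected so typos do not pass silently.
#'
#' @param path Path to a YAML file.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("constants", "constructs", "traps", "handle", "hmm", "fit",
             "scenarios", "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in c("constants", "traps", "handle")) {
    vals <- unlist(cfg[[key]])
    if (!is.null(vals) && any(is.numeric(vals) & vals <= 0)) {
      stop("configuration section '", key, "' contains non-positive values",
           call. = FALSE)
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write analysis results as JSON
#'
#' Serialises a named list or tibble of results with unit-suffixed field
#' names to JSON, without rounding.
#'
#' @param results Named list or data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Published template-complex parameter table
#'
#' Per-mutant measurements of the neuronal template complex shipped with the
#' package: unfolding energy with its standard error, equilibrium force,
#' zero-force folding and unfolding rates, formation and SNAP-25-binding
#' probabilities, and observation counts. Energies below the 1.5 kBT
#' detection limit are censored (`censored = TRUE`, energy `NA`).
#'
#' @return A tibble with one row per construct variant.
#' @export
#' @examples
#' params <- template_complex_params()
#' params[params$mutation == "WT", ]
template_complex_params <- function() {
  path <- system.file("extdata", "template_complex_params.tsv",
                      package = "tweezerfold", mustWork = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  dplyr::mutate(df, censored = !is.finite(.data$unfolding_energy_kbt))
}
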
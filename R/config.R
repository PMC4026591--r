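#' Tracking-session configuration
#'
#' Builds the policy object that governs a tracking session: how the random
#' number generator is initialised, where details and archives go, which
#' files are copied into the archive, and which events are recorded at all.
#' Every option has a default, so `begin_tracking()` can be called with an
#' empty configuration.
#'
#' @param rng_init A list with components `seed` (integer), and optionally
#'   `kind` and `normal_kind` (generator names understood by [set.seed()]).
#'   The session seeds the RNG from this before the workload runs, so that
#'   stochastic computations can be replayed exactly. Default seed is
#'   `123456789` with the interpreter's default generators.
#' @param details_file Base name of the serialized details file written into
#'   the archive. Default `"rc.details.rds"`.
#' @param archive_folder Optional base name for the archive directory. When
#'   `NULL` the archive is named by the timestamp alone
#'   (`YYYY-MM-DD-HH-MM-SS`); otherwise `<archive_folder>-YYYY-MM-DD-HH-MM-SS`.
#' @param maxsize_archive Maximum size, in bytes, of an *input* file that
#'   will be copied into the archive. Larger inputs are still recorded in
#'   the manifest but not copied (`skip_reason = "too_large"`). Outputs are
#'   copied regardless of size. Default `1e9` (1 GB).
#' @param do_not_archive Character vector of file extensions (with or
#'   without the leading dot, matched case-insensitively). Matching files —
#'   inputs and outputs alike — are recorded but never copied
#'   (`skip_reason = "extension_excluded"`). Useful for bulky per-sample raw
#'   data files that live elsewhere.
#' @param skip_file_calls Character vector of function names. A file-open
#'   event is silently dropped when any frame of its call stack matches one
#'   of these names. The default suppresses the package-loading machinery
#'   (`library`, `require`, `loadNamespace`, `requireNamespace`), whose many
#'   low-level file touches are already documented by the environment
#'   snapshot.
#' @param skip_empty_description Logical; drop file-open events whose file
#'   description is empty (technical connection calls that name no file).
#'   Default `TRUE`.
#' @param rng_trace Logical; when `TRUE` (default) every call to a function
#'   in `rng_functions` is recorded. When `FALSE` only the initial seed
#'   record is kept, which speeds up simulation-heavy workloads.
#' @param rng_functions Character vector of random-number generator names to
#'   monitor. Default `c("runif", "rnorm", "sample")` — uniform, normal, and
#'   integer sampling/permutation. `sample.int` is not listed by default
#'   because `sample()` calls it internally and monitoring both would record
#'   one user-level draw twice.
#' @param print_trace Logical; emit progress messages while tracking.
#'   Default `FALSE`.
#'
#' @return An object of class `tracker_config` (a validated named list).
#' @seealso [begin_tracking()], [load_config()]
#' @examples
#' tracker_config()
#' tracker_config(rng_init = list(seed = 42), maxsize_archive = 1e6)
#' @export
tracker_config <- function(rng_init = list(seed = 123456789L,
                                           kind = NULL,
                                           normal_kind = NULL),
                           details_file = "rc.details.rds",
                           archive_folder = NULL,
                           maxsize_archive = 1e9,
                           do_not_archive = character(),
                           skip_file_calls = c("library", "require",
                                               "loadNamespace",
                                               "requireNamespace"),
                           skip_empty_description = TRUE,
                           rng_trace = TRUE,
                           rng_functions = c("runif", "rnorm", "sample"),
                           print_trace = FALSE) {
  cfg <- structure(
    list(rng_init = rng_init,
         details_file = details_file,
         archive_folder = archive_folder,
         maxsize_archive = maxsize_archive,
         do_not_archive = do_not_archive,
         skip_file_calls = skip_file_calls,
         skip_empty_description = skip_empty_description,
         rng_trace = rng_trace,
         rng_functions = rng_functions,
         print_trace = print_trace),
    class = "tracker_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "tracker_config"))
  if (!is.null(cfg$rng_init)) {
    if (!is.list(cfg$rng_init) || is.null(cfg$rng_init$seed))
      stop("'rng_init' must be a list with at least a 'seed' component",
           call. = FALSE)
    seed <- cfg$rng_init$seed
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
        seed != as.integer(seed))
      stop("'rng_init$seed' must be a single integer", call. = FALSE)
    cfg$rng_init$seed <- as.integer(seed)
  }
  if (!is.character(cfg$details_file) || length(cfg$details_file) != 1L ||
      !nzchar(cfg$details_file))
    stop("'details_file' must be a non-empty file name", call. = FALSE)
  if (!is.null(cfg$archive_folder)) {
    if (!is.character(cfg$archive_folder) ||
        length(cfg$archive_folder) != 1L)
      stop("'archive_folder' must be a single name or NULL", call. = FALSE)
    if (grepl("[/\\\\]", cfg$archive_folder))
      stop("'archive_folder' must be a bare name without path separators",
           call. = FALSE)
  }
  if (!is.numeric(cfg$maxsize_archive) ||
      length(cfg$maxsize_archive) != 1L || is.na(cfg$maxsize_archive) ||
      cfg$maxsize_archive < 0)
    stop("'maxsize_archive' must be a single non-negative number of bytes",
         call. = FALSE)
  if (!is.character(cfg$do_not_archive))
    stop("'do_not_archive' must be a character vector of extensions",
         call. = FALSE)
  if (any(!nzchar(sub("^\\.", "", cfg$do_not_archive))))
    stop("every extension in 'do_not_archive' must be non-empty",
         call. = FALSE)
  if (!is.character(cfg$skip_file_calls))
    stop("'skip_file_calls' must be a character vector", call. = FALSE)
  for (fld in c("skip_empty_description", "rng_trace", "print_trace")) {
    v <- cfg[[fld]]
    if (!is.logical(v) || length(v) != 1L || is.na(v))
      stop(sprintf("'%s' must be TRUE or FALSE", fld), call. = FALSE)
  }
  if (!is.character(cfg$rng_functions))
    stop("'rng_functions' must be a character vector of function names",
         call. = FALSE)
  cfg
}

#' @export
print.tracker_config <- function(x, ...) {
  cat("<tracker_config>\n")
  seed <- if (is.null(x$rng_init)) "default" else x$rng_init$seed
  cat("  rng seed:              ", seed, "\n")
  cat("  details file:          ", x$details_file, "\n")
  cat("  archive folder base:   ",
      if (is.null(x$archive_folder)) "<timestamp only>" else x$archive_folder,
      "\n")
  cat("  max archived input:    ", format(x$maxsize_archive, big.mark = ","),
      "bytes\n")
  cat("  excluded extensions:   ",
      if (length(x$do_not_archive)) paste(x$do_not_archive, collapse = ", ")
      else "<none>", "\n")
  cat("  skipped call names:    ",
      paste(x$skip_file_calls, collapse = ", "), "\n")
  cat("  skip empty description:", x$skip_empty_description, "\n")
  cat("  rng trace:             ", x$rng_trace,
      " (", paste(x$rng_functions, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# keys accepted in config files / CLI flags, mapped onto tracker_config()
.config_keys <- c("seed", "rng_kind", "rng_normal_kind", "details_file",
                  "archive_folder", "maxsize_archive", "do_not_archive",
                  "skip_file_calls", "skip_empty_description", "rng_trace",
                  "rng_functions", "print_trace")

#' Load a tracking configuration from a file and/or flag overrides
#'
#' Reads a flat YAML key-value file whose keys mirror the session options
#' (`seed`, `rng_kind`, `rng_normal_kind`, `details_file`, `archive_folder`,
#' `maxsize_archive`, `do_not_archive`, `skip_file_calls`,
#' `skip_empty_description`, `rng_trace`, `rng_functions`, `print_trace`),
#' then applies `flags` on top. Precedence: flags override file values, which
#' override the defaults of [tracker_config()]. Unknown keys are rejected
#' with an error naming the key.
#'
#' @param file Path to a YAML configuration file, or `NULL`.
#' @param flags Named list of overrides using the same keys.
#' @return A validated [tracker_config()] object.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("seed: 7", "maxsize_archive: 1048576"), f)
#' load_config(f, flags = list(seed = 99))$rng_init$seed
#' @export
load_config <- function(file = NULL, flags = list()) {
  vals <- list()
  if (!is.null(file)) {
    if (!file.exists(file))
      stop("config file not found: ", file, call. = FALSE)
    parsed <- tryCatch(yaml::read_yaml(file), error = function(e)
      stop("malformed config file '", file, "': ", conditionMessage(e),
           call. = FALSE))
    if (is.null(parsed)) parsed <- list()
    if (!is.list(parsed) || (length(parsed) && is.null(names(parsed))))
      stop("config file must be a flat key: value mapping", call. = FALSE)
    vals <- parsed
  }
  if (length(flags)) {
    if (is.null(names(flags)) || any(!nzchar(names(flags))))
      stop("'flags' must be a fully named list", call. = FALSE)
    vals[names(flags)] <- flags
  }
  unknown <- setdiff(names(vals), .config_keys)
  if (length(unknown))
    stop("unknown configuration key: ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)

  for (key in c("seed", "maxsize_archive")) {
    if (!is.null(vals[[key]])) {
      v <- suppressWarnings(as.numeric(vals[[key]]))
      if (length(v) != 1L || is.na(v))
        stop("configuration key '", key, "' must be a number", call. = FALSE)
      vals[[key]] <- v
    }
  }
  for (key in c("skip_empty_description", "rng_trace", "print_trace")) {
    if (!is.null(vals[[key]])) vals[[key]] <- .as_flag(vals[[key]], key)
  }
  for (key in c("do_not_archive", "skip_file_calls", "rng_functions")) {
    if (!is.null(vals[[key]]))
      vals[[key]] <- .split_csv(as.character(vals[[key]]))
  }

  args <- list()
  if (!is.null(vals$seed) || !is.null(vals$rng_kind) ||
      !is.null(vals$rng_normal_kind)) {
    args$rng_init <- list(
      seed = if (is.null(vals$seed)) 123456789L else as.integer(vals$seed),
      kind = vals$rng_kind,
      normal_kind = vals$rng_normal_kind)
  }
  for (key in c("details_file", "archive_folder", "maxsize_archive",
                "do_not_archive", "skip_file_calls",
                "skip_empty_description", "rng_trace", "rng_functions",
                "print_trace")) {
    if (!is.null(vals[[key]])) args[[key]] <- vals[[key]]
  }
  do.call(tracker_config, args)
}

.as_flag <- function(v, key) {
  out <- if (is.logical(v)) v else
    switch(tolower(as.character(v)),
           "true" = , "yes" = , "1" = TRUE,
           "false" = , "no" = , "0" = FALSE,
           NA)
  if (length(out) != 1L || is.na(out))
    stop("configuration key '", key, "' must be TRUE or FALSE",
         call. = FALSE)
  out
}

.split_csv <- function(x) {
  x <- unlist(strsplit(x, ",", fixed = TRUE), use.names = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}
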
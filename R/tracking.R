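# Session state lives in the package namespace: one tracking session per
# process, mirroring a single dedicated detail-store environment.
.rc_state <- new.env(parent = emptyenv())
.rc_state$session <- NULL

# graphics devices that open an output file at the call site; value is the
# name of the formal argument holding the file name
.graphics_devices <- c(jpeg = "filename", png = "filename", bmp = "filename",
                       tiff = "filename", pdf = "file", svg = "file",
                       postscript = "file", cairo_pdf = "file")
.connection_openers <- c("file", "gzfile")
.system_functions <- c("system", "system2")

#' Is a tracking session active?
#' @return `TRUE` if a session started by [begin_tracking()] has not yet
#'   been closed by [end_tracking()].
#' @export
tracking_active <- function() !is.null(.rc_state$session)

#' Start a provenance-tracking session
#'
#' Seeds the random number generator, creates the in-memory detail store,
#' and embeds detail-collection hooks into the functions that open files
#' for reading or writing (`file`, `gzfile`, and the file-producing
#' graphics devices), generate random numbers (per
#' `config$rng_functions`, when `config$rng_trace` is `TRUE`), and issue
#' system calls (`system`, `system2`). The hooks run transparently: the
#' monitored functions return exactly what they would untracked, and the
#' user script needs no modification. Hooks stay in place until
#' [end_tracking()] removes them.
#'
#' The first record of the session's random details is always the
#' seed-initialization event carrying the starting seed and the generator
#' kinds, so that stochastic computations can be replayed.
#'
#' @param config A [tracker_config()] object.
#' @return The session handle (class `rc_session`), invisibly. Only one
#'   session may be active per process; starting a second one is an error.
#' @seealso [end_tracking()], [run_tracked()]
#' @export
begin_tracking <- function(config = tracker_config()) {
  if (tracking_active())
    stop("a tracking session is already active; call end_tracking() first",
         call. = FALSE)
  config <- validate_config(config)

  rng <- config$rng_init
  if (is.null(rng)) rng <- list(seed = 123456789L)
  do.call(set.seed, c(list(seed = rng$seed),
                      if (!is.null(rng$kind)) list(kind = rng$kind),
                      if (!is.null(rng$normal_kind))
                        list(normal.kind = rng$normal_kind)))

  session <- new.env(parent = emptyenv())
  class(session) <- "rc_session"
  session$config <- config
  session$session_start <- Sys.time()
  session$session_end <- NULL
  session$file_details <- list()
  session$random_details <- list()
  session$system_calls <- list()
  session$roles <- new.env(parent = emptyenv())  # full_path -> "input"/"output"
  session$script_path <- NULL
  session$counter <- 0L
  session$active <- TRUE
  session$traced <- list()

  # seed-initialization record, sketched from the live call stack
  stack <- .stack_names(sys.calls(), "begin_tracking")
  sk <- sketch_call_stack(stack)
  session$counter <- session$counter + 1L
  session$random_details[[1L]] <- list(
    top_call = sk[["top_call"]], mid_call = sk[["mid_call"]],
    bot_call = sk[["bot_call"]], call_time = Sys.time(),
    seq = session$counter,
    seed = rng$seed, kind = RNGkind()[1L], normal_kind = RNGkind()[2L],
    full_call = paste(deparse(sys.call()), collapse = " "))

  .rc_state$session <- session
  ok <- tryCatch({
    .install_hooks(session, config)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    .remove_hooks(session)
    .rc_state$session <- NULL
    stop("failed to install tracking hooks: ", conditionMessage(ok),
         call. = FALSE)
  }
  if (config$print_trace)
    message("provtrack: session started (seed ", rng$seed, ")")
  invisible(session)
}

#' End a tracking session and build its archive
#'
#' Removes every detail-collection hook (restoring the original function
#' definitions, so subsequent file or RNG activity is not recorded),
#' snapshots the computing environment, and materialises the session into a
#' timestamped read-only archive directory containing copies of the
#' accessed files, the MD5 manifest, the serialized details and a
#' plain-text appendix. See [build_archive()] for the archive layout.
#'
#' @param dir Parent directory in which the archive directory is created.
#'   Defaults to the working directory.
#' @return The archive directory path, with the [build_archive()] manifest
#'   attached as attribute `"manifest"`.
#' @export
end_tracking <- function(dir = ".") {
  session <- .rc_state$session
  if (is.null(session))
    stop("no tracking session is active", call. = FALSE)
  .remove_hooks(session)
  .rc_state$session <- NULL
  session$session_end <- Sys.time()
  session$environment <- .environment_snapshot()
  manifest <- build_archive(session, session$config, dir = dir)
  session$active <- FALSE
  if (session$config$print_trace)
    message("provtrack: archive written to ", manifest$archive_path)
  structure(manifest$archive_path, manifest = manifest)
}

# ---- hook installation -----------------------------------------------------

# Hooks are installed with where = globalenv(): the tracing machinery then
# locates the function on the search path and patches both the attached
# package environment and the owning namespace, so calls from the user
# script and from package internals (e.g. write.table -> file) are both
# intercepted. Functions that do not exist in this build are skipped.
.install_one <- function(session, name, tracer) {
  ok <- tryCatch({
    suppressMessages(trace(name, tracer = tracer, print = FALSE,
                           where = globalenv()))
    TRUE
  }, error = function(e) FALSE)
  if (ok)
    session$traced[[length(session$traced) + 1L]] <- name
  invisible(ok)
}

.install_hooks <- function(session, config) {
  for (nm in .connection_openers)
    .install_one(session, nm,
                 bquote(provtrack:::.ev_file(.(nm), description, open)))
  for (nm in names(.graphics_devices)) {
    arg <- as.name(.graphics_devices[[nm]])
    .install_one(session, nm,
                 bquote(provtrack:::.ev_file(.(nm), .(arg), "w")))
  }
  if (isTRUE(config$rng_trace))
    for (nm in unique(config$rng_functions))
      .install_one(session, nm, bquote(provtrack:::.ev_rng(.(nm))))
  .install_one(session, "system",
               quote(provtrack:::.ev_sys("system", command)))
  .install_one(session, "system2",
               quote(provtrack:::.ev_sys("system2",
                                         paste(c(command, args),
                                               collapse = " "))))
  invisible(NULL)
}

.remove_hooks <- function(session) {
  for (nm in session$traced)
    try(suppressMessages(untrace(nm, where = globalenv())), silent = TRUE)
  session$traced <- list()
  invisible(NULL)
}

# ---- call-stack handling ---------------------------------------------------

.call_name <- function(cl) {
  f <- cl[[1L]]
  if (is.name(f)) return(as.character(f))
  if (is.call(f) && length(f) == 3L &&
      as.character(f[[1L]]) %in% c("::", ":::"))
    return(as.character(f[[3L]]))
  "<anonymous>"
}

# Names of the user-visible stack, outermost first, truncated at the
# innermost occurrence of the intercepted function `what` (frames below it
# belong to the tracing machinery).
.stack_names <- function(calls, what) {
  if (!length(calls)) return(what)
  nm <- vapply(calls, .call_name, character(1L))
  hit <- which(nm == what)
  n <- if (length(hit)) max(hit) else {
    machinery <- c(".doTrace", "doTrace", "eval", "eval.parent", "evalq",
                   "tryCatch", "tryCatchList", "tryCatchOne",
                   ".ev_file", ".ev_rng", ".ev_sys", ".stack_names")
    keep <- which(!nm %in% machinery)
    if (length(keep)) max(keep) else length(nm)
  }
  nm[seq_len(n)]
}

#' Sketch a call stack as its top, middle and bottom calls
#'
#' Compresses a call stack into the three-element summary stored with every
#' provenance record: the outermost call (`top_call`), the intercepted
#' primitive at the bottom (`bot_call`), and the immediate caller of that
#' primitive (`mid_call`). For stacks shallower than three frames the
#' available frames repeat, so a depth-one stack yields three identical
#' names.
#'
#' @param stack Character vector of function names, outermost first.
#' @return Named character vector with elements `top_call`, `mid_call`,
#'   `bot_call`.
#' @examples
#' sketch_call_stack(c("Sweave", "source", "file"))
#' sketch_call_stack("begin_tracking")
#' @export
sketch_call_stack <- function(stack) {
  if (!is.character(stack) || length(stack) == 0L || any(!nzchar(stack)))
    stop("'stack' must be a non-empty character vector of function names",
         call. = FALSE)
  k <- length(stack)
  c(top_call = stack[1L],
    mid_call = stack[max(k - 1L, 1L)],
    bot_call = stack[k])
}

# ---- event handlers (run inside the traced functions) ----------------------

.ev_file <- function(what, description, open) {
  s <- .rc_state$session
  if (is.null(s)) return(invisible(NULL))
  tryCatch({
    desc <- tryCatch(as.character(description)[1L], error = function(e) "")
    if (length(desc) != 1L || is.na(desc)) desc <- ""
    mode <- tryCatch(as.character(open)[1L], error = function(e) "")
    if (length(mode) != 1L || is.na(mode)) mode <- ""
    calls <- sys.calls()
    stack <- .stack_names(calls, what)
    full_call <- paste(deparse(calls[[min(length(stack),
                                          length(calls))]]),
                       collapse = " ")
    record_file_access(desc, mode, stack, full_call = full_call)
  }, error = function(e) {
    if (isTRUE(s$config$print_trace))
      message("provtrack: file hook error: ", conditionMessage(e))
    NULL
  })
  invisible(NULL)
}

.ev_rng <- function(what) {
  s <- .rc_state$session
  if (is.null(s)) return(invisible(NULL))
  tryCatch({
    stack <- .stack_names(sys.calls(), what)
    record_random_event(what, stack)
  }, error = function(e) NULL)
  invisible(NULL)
}

.ev_sys <- function(what, command) {
  s <- .rc_state$session
  if (is.null(s)) return(invisible(NULL))
  tryCatch({
    cmd <- paste(as.character(command), collapse = " ")
    stack <- .stack_names(sys.calls(), what)
    record_system_call(cmd, stack)
  }, error = function(e) NULL)
  invisible(NULL)
}

# ---- record operations -----------------------------------------------------

#' Record a file-access event in the active session
#'
#' Appends a file-access record unless suppressed by session policy: no
#' record is made when any frame of `stack` matches
#' `skip_file_calls`, or when `path` is empty and
#' `skip_empty_description` is set. Modes containing a write or append
#' intent (`w`, `a`, `+`) classify as write-like and mark the path as a
#' session output to be preserved; every other mode is read-like and marks
#' an input. Normally called by the embedded hooks; exported so that the
#' recording policy can be exercised directly.
#'
#' @param path File description as given at the call site (usually a file
#'   name; may be relative).
#' @param mode Open mode string, e.g. `"r"`, `"w"`, `"rt"`, `"rb"`.
#' @param stack Character vector of function names, outermost first.
#' @param full_call Optional verbatim text of the invoking call.
#' @return The appended record (a named list), invisibly, or `NULL` when
#'   the event was suppressed.
#' @export
record_file_access <- function(path, mode, stack, full_call = NULL) {
  s <- .rc_state$session
  if (is.null(s)) stop("no tracking session is active", call. = FALSE)
  cfg <- s$config
  if (any(stack %in% cfg$skip_file_calls)) return(invisible(NULL))
  if (!nzchar(path) && isTRUE(cfg$skip_empty_description))
    return(invisible(NULL))
  sk <- sketch_call_stack(stack)
  full_path <- if (nzchar(path)) .abs_path(path) else ""
  write_like <- .is_write_mode(mode)
  s$counter <- s$counter + 1L
  rec <- list(top_call = sk[["top_call"]], mid_call = sk[["mid_call"]],
              bot_call = sk[["bot_call"]], call_time = Sys.time(),
              seq = s$counter, description = path, open = mode,
              full_call = if (is.null(full_call)) "" else full_call,
              full_path = full_path)
  s$file_details[[length(s$file_details) + 1L]] <- rec
  if (nzchar(full_path)) {
    prev <- if (exists(full_path, envir = s$roles, inherits = FALSE))
      get(full_path, envir = s$roles) else NULL
    role <- if (write_like || identical(prev, "output")) "output" else "input"
    assign(full_path, role, envir = s$roles)
  }
  if (isTRUE(cfg$print_trace))
    message("provtrack: ", if (write_like) "write" else "read", " ", path)
  invisible(rec)
}

# write/append/update intents are write-like; everything else (including
# the lazy "" mode of an unopened connection) is read-like
.is_write_mode <- function(mode) grepl("[wa+]", mode)

# Stable absolute form of a path that may not exist yet (normalizePath
# leaves nonexistent relative paths untouched, which would defeat
# de-duplication of a file that is first written and later read).
.abs_path <- function(path) {
  if (!grepl("^(/|~|[A-Za-z]:)", path))
    path <- file.path(getwd(), path)
  normalizePath(path, winslash = "/", mustWork = FALSE)
}

#' Record a random-number-generation event in the active session
#'
#' Appends a record only when RNG tracing is enabled and `function_name`
#' is one of the monitored generators. Generation events leave the seed
#' and generator fields empty — those are carried only by the session's
#' seed-initialization record.
#'
#' @param function_name Name of the generator that fired.
#' @param stack Character vector of function names, outermost first.
#' @return The appended record invisibly, or `NULL` when not recorded.
#' @export
record_random_event <- function(function_name, stack) {
  s <- .rc_state$session
  if (is.null(s)) stop("no tracking session is active", call. = FALSE)
  cfg <- s$config
  if (!isTRUE(cfg$rng_trace) || !(function_name %in% cfg$rng_functions))
    return(invisible(NULL))
  sk <- sketch_call_stack(stack)
  s$counter <- s$counter + 1L
  rec <- list(top_call = sk[["top_call"]], mid_call = sk[["mid_call"]],
              bot_call = sk[["bot_call"]], call_time = Sys.time(),
              seq = s$counter, seed = NA_integer_, kind = NA_character_,
              normal_kind = NA_character_, full_call = "")
  s$random_details[[length(s$random_details) + 1L]] <- rec
  invisible(rec)
}

#' Record an external system call in the active session
#'
#' The command line is stored verbatim with a call-stack sketch; no attempt
#' is made to introspect what the external process does (its own file
#' accesses are invisible to the session).
#'
#' @param command The command string passed to the system.
#' @param stack Character vector of function names, outermost first.
#' @return The appended record, invisibly.
#' @export
record_system_call <- function(command, stack) {
  s <- .rc_state$session
  if (is.null(s)) stop("no tracking session is active", call. = FALSE)
  if (!is.character(command) || length(command) != 1L || !nzchar(command))
    stop("'command' must be a non-empty string", call. = FALSE)
  sk <- sketch_call_stack(stack)
  s$counter <- s$counter + 1L
  rec <- list(top_call = sk[["top_call"]], mid_call = sk[["mid_call"]],
              bot_call = sk[["bot_call"]], call_time = Sys.time(),
              seq = s$counter, command = command)
  s$system_calls[[length(s$system_calls) + 1L]] <- rec
  invisible(rec)
}

# ---- environment snapshot --------------------------------------------------

.environment_snapshot <- function() {
  si <- utils::sessionInfo()
  pkgs <- c(si$otherPkgs, si$loadedOnly)
  loaded <- if (length(pkgs)) {
    data.frame(name = vapply(pkgs, function(p) p$Package, character(1L)),
               version = vapply(pkgs, function(p) as.character(p$Version),
                                character(1L)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(), version = character(),
               stringsAsFactors = FALSE)
  }
  loaded <- loaded[order(loaded$name), , drop = FALSE]
  mem <- sum(gc(FALSE)[, 2L]) * 2^20  # both generations, Mb -> bytes
  list(interpreter_version = R.version.string,
       loaded_packages = loaded,
       platform_info = as.list(Sys.info()),
       command_args = commandArgs(),
       memory_usage = round(mem),
       capture_time = Sys.time())
}

# ---- accessors -------------------------------------------------------------

.records_df <- function(records, fields) {
  cols <- lapply(fields, function(f) {
    vals <- lapply(records, `[[`, f)
    if (f == "call_time") {
      out <- as.POSIXct(unlist(lapply(vals, as.numeric)),
                        origin = "1970-01-01")
      if (!length(records)) out <- as.POSIXct(character())
      out
    } else if (f %in% c("seq", "seed")) {
      if (!length(records)) integer() else
        vapply(vals, function(v) if (is.null(v)) NA_integer_ else
          as.integer(v), integer(1L))
    } else {
      if (!length(records)) character() else
        vapply(vals, function(v) if (is.null(v)) NA_character_ else
          as.character(v), character(1L))
    }
  })
  names(cols) <- fields
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Session detail tables
#'
#' Extract the accumulated provenance records of a session (or of a details
#' document read back with [read_details()]) as data frames, one row per
#' event in call order.
#'
#' @param x An `rc_session` handle or an `rc_details` list.
#' @return A data frame. `file_details()` has columns `top_call`,
#'   `mid_call`, `bot_call`, `call_time`, `description`, `open`,
#'   `full_call`, `full_path`; `random_details()` has the sketch and time
#'   columns plus `seed`, `kind`, `normal_kind`;
#'   `system_call_details()` has the sketch and time columns plus
#'   `command`.
#' @export
file_details <- function(x) {
  .records_df(.detail_records(x, "file_details"),
              c("top_call", "mid_call", "bot_call", "call_time",
                "description", "open", "full_call", "full_path"))
}

#' @rdname file_details
#' @export
random_details <- function(x) {
  .records_df(.detail_records(x, "random_details"),
              c("top_call", "mid_call", "bot_call", "call_time",
                "seed", "kind", "normal_kind"))
}

#' @rdname file_details
#' @export
system_call_details <- function(x) {
  .records_df(.detail_records(x, "system_calls"),
              c("top_call", "mid_call", "bot_call", "call_time", "command"))
}

.detail_records <- function(x, field) {
  if (inherits(x, "rc_session")) return(x[[field]])
  if (is.list(x) && !is.null(x[[field]])) return(x[[field]])
  if (is.list(x)) return(list())
  stop("cannot extract detail records from an object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

#' @export
print.rc_session <- function(x, ...) {
  cat("<provenance tracking session>\n")
  cat("  started: ", format(x$session_start), "\n", sep = "")
  cat("  status:  ",
      if (isTRUE(x$active)) "active" else "ended", "\n", sep = "")
  cat("  file-access records:  ", length(x$file_details), "\n")
  cat("  random-event records: ", length(x$random_details), "\n")
  cat("  system-call records:  ", length(x$system_calls), "\n")
  invisible(x)
}
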
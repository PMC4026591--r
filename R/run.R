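#' Run an unmodified analysis script under provenance tracking
#'
#' Equivalent to [begin_tracking()], `source(script)`, [end_tracking()]:
#' the script needs no modification, its own file reads/writes, random
#' draws and system calls are recorded, and the script file itself is
#' recorded as a read and archived with role `code`. If the script raises
#' an error, whatever details were collected up to that point are still
#' archived, and the error is then re-signalled as a classed condition
#' (`provtrack_script_error`) carrying the archive path in its `archive`
#' field.
#'
#' @param script Path to an R script.
#' @param config A [tracker_config()].
#' @param workdir Working directory for the run; relative paths in the
#'   script resolve here and the archive is created here. Defaults to the
#'   script's directory.
#' @return The archive path (manifest attached as attribute
#'   `"manifest"`).
#' @examples
#' wl <- make_worked_example(tempfile("ex-"))
#' archive <- run_tracked(wl$script, tracker_config(archive_folder = "run"))
#' basename(archive)
#' @export
run_tracked <- function(script, config = tracker_config(),
                        workdir = dirname(script)) {
  if (!is.character(script) || length(script) != 1L ||
      !file.exists(script))
    stop("script not found: ", script, call. = FALSE)
  script <- normalizePath(script, winslash = "/")
  old <- setwd(workdir)
  on.exit(setwd(old), add = TRUE)
  on.exit({  # never leave hooks behind, whatever happens below
    if (tracking_active()) {
      .remove_hooks(.rc_state$session)
      .rc_state$session <- NULL
    }
  }, add = TRUE)

  begin_tracking(config)
  .rc_state$session$script_path <- script
  err <- NULL
  tryCatch(
    source(script, local = new.env(parent = globalenv()),
           keep.source = FALSE),
    error = function(e) err <<- e)
  archive <- end_tracking(dir = ".")
  archive <- structure(normalizePath(archive, winslash = "/"),
                       manifest = attr(archive, "manifest"))
  if (!is.null(err)) {
    cond <- structure(
      class = c("provtrack_script_error", "error", "condition"),
      list(message = paste0("tracked script failed: ",
                            conditionMessage(err)),
           call = conditionCall(err), archive = archive))
    stop(cond)
  }
  archive
}

# ---- command-line interface ------------------------------------------------

.cli_usage <- c(
  "usage: provtrack <command> [options]",
  "",
  "commands:",
  "  run <script.R>        run a script under tracking, build its archive",
  "  check <archive-dir>   audit an archive against its manifest",
  "  compare <dir> <dir>   compare two archives",
  "  checkzip <file.zip>   audit a zip archive against its embedded manifest",
  "  appendix <archive>    print the plain-text appendix of an archive",
  "",
  "options for run:",
  "  --config <file>       YAML configuration file",
  "  --seed <int>          initial RNG seed",
  "  --archive-folder <s>  archive directory base name",
  "  --maxsize <bytes>     maximum archived input size",
  "  --do-not-archive ext[,ext...]  extensions never copied",
  "  --details-file <name> name of the serialized details file",
  "  --no-rng-trace        record only the initial seed",
  "  --print-trace         emit progress messages",
  "  --workdir <dir>       working directory for the run",
  "options for check/compare/checkzip:",
  "  --out <file>          also write the report as a TSV table")

.cli_value_flags <- c("--config", "--seed", "--archive-folder", "--maxsize",
                      "--do-not-archive", "--details-file", "--workdir",
                      "--out")
.cli_bool_flags <- c("--no-rng-trace", "--print-trace")

.parse_cli <- function(args) {
  opts <- list()
  pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--[a-z-]+=", a)) {
      key <- sub("=.*$", "", a)
      val <- sub("^[^=]*=", "", a)
      if (!(key %in% .cli_value_flags))
        stop("unknown option: ", key, call. = FALSE)
      opts[[key]] <- val
    } else if (a %in% .cli_value_flags) {
      if (i == length(args))
        stop("option ", a, " needs a value", call. = FALSE)
      opts[[a]] <- args[i + 1L]
      i <- i + 1L
    } else if (a %in% .cli_bool_flags) {
      opts[[a]] <- TRUE
    } else if (grepl("^--", a)) {
      stop("unknown option: ", a, call. = FALSE)
    } else {
      pos <- c(pos, a)
    }
    i <- i + 1L
  }
  list(opts = opts, pos = pos)
}

.cli_config <- function(opts) {
  flags <- list()
  if (!is.null(opts[["--seed"]])) flags$seed <- opts[["--seed"]]
  if (!is.null(opts[["--archive-folder"]]))
    flags$archive_folder <- opts[["--archive-folder"]]
  if (!is.null(opts[["--maxsize"]]))
    flags$maxsize_archive <- opts[["--maxsize"]]
  if (!is.null(opts[["--do-not-archive"]]))
    flags$do_not_archive <- opts[["--do-not-archive"]]
  if (!is.null(opts[["--details-file"]]))
    flags$details_file <- opts[["--details-file"]]
  if (isTRUE(opts[["--no-rng-trace"]])) flags$rng_trace <- FALSE
  if (isTRUE(opts[["--print-trace"]])) flags$print_trace <- TRUE
  load_config(opts[["--config"]], flags)
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the `provtrack` shell tool (see
#' `inst/exec/provtrack`): `run`, `check`, `compare`, `checkzip`,
#' `appendix`. Audit subcommands exit with status 0 only when the report
#' contains zero discrepancies, so archives can be verified from shell
#' scripts.
#'
#' @param args Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer process exit status (0 on success), invisibly.
#' @export
provtrack_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("-h", "--help", "help")) {
    writeLines(.cli_usage)
    return(invisible(0L))
  }
  cmd <- args[1L]
  parsed <- tryCatch(.parse_cli(args[-1L]), error = function(e) e)
  if (inherits(parsed, "error")) {
    message("provtrack: ", conditionMessage(parsed))
    return(invisible(2L))
  }
  opts <- parsed$opts
  pos <- parsed$pos

  need <- function(n, what) {
    if (length(pos) < n) {
      message("provtrack: ", cmd, " requires ", what)
      return(FALSE)
    }
    TRUE
  }
  report_out <- function(report) {
    if (!is.null(opts[["--out"]]))
      .write_tsv(as.data.frame(report), opts[["--out"]])
    print(report)
    invisible(if (n_discrepancies(report) == 0L) 0L else 1L)
  }

  status <- tryCatch(switch(
    cmd,
    run = {
      if (!need(1L, "a script path")) return(invisible(2L))
      cfg <- .cli_config(opts)
      workdir <- if (!is.null(opts[["--workdir"]])) opts[["--workdir"]]
                 else dirname(pos[1L])
      res <- tryCatch(run_tracked(pos[1L], cfg, workdir = workdir),
                      provtrack_script_error = function(e) e)
      if (inherits(res, "provtrack_script_error")) {
        message("provtrack: ", conditionMessage(res))
        message("provtrack: partial archive: ", res$archive)
        1L
      } else {
        cat("archive:", res, "\n")
        0L
      }
    },
    check = {
      if (!need(1L, "an archive directory")) return(invisible(2L))
      report_out(check_archive(pos[1L]))
    },
    compare = {
      if (!need(2L, "two archive directories")) return(invisible(2L))
      report_out(compare_archives(pos[1L], pos[2L]))
    },
    checkzip = {
      if (!need(1L, "a zip file")) return(invisible(2L))
      report_out(check_zipfile(pos[1L]))
    },
    appendix = {
      if (!need(1L, "an archive directory or details file"))
        return(invisible(2L))
      writeLines(render_appendix(read_details(pos[1L])))
      0L
    },
    {
      message("provtrack: unknown command '", cmd, "'")
      writeLines(.cli_usage)
      2L
    }), error = function(e) {
      message("provtrack: ", conditionMessage(e))
      2L
    })
  invisible(as.integer(status))
}
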
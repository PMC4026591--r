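# Files every archive contains besides the copied workload files.
.reserved_names <- function(config)
  c(config$details_file, "MANIFEST.tsv", "APPENDIX.txt",
    "rc.file.details.tsv", "rc.random.details.tsv")

.details_format_version <- "1.0"

#' Timestamped archive directory name
#'
#' Archive directories are named `YYYY-MM-DD-HH-MM-SS`, or
#' `<base>-YYYY-MM-DD-HH-MM-SS` when a base name is configured, so that the
#' name itself identifies the version of the analysis. When `dir` is given
#' and the name already exists there, a deterministic numeric suffix
#' (`-2`, `-3`, ...) is appended so consecutive builds never overwrite an
#' existing archive.
#'
#' @param base Optional base name; must not contain path separators.
#' @param timestamp A `POSIXct` time; defaults to now.
#' @param dir Optional parent directory against which to uniquify.
#' @return The directory name (not a full path).
#' @examples
#' archive_name("mydir", as.POSIXct("2014-03-27 14:52:14"))
#' @export
archive_name <- function(base = NULL, timestamp = Sys.time(), dir = NULL) {
  if (!inherits(timestamp, c("POSIXct", "POSIXlt")))
    stop("'timestamp' must be a date-time", call. = FALSE)
  stamp <- format(timestamp, "%Y-%m-%d-%H-%M-%S")
  if (!is.null(base)) {
    if (!is.character(base) || length(base) != 1L || !nzchar(base))
      stop("'base' must be a single non-empty name", call. = FALSE)
    if (grepl("[/\\\\]", base))
      stop("'base' must not contain path separators", call. = FALSE)
    stamp <- paste0(base, "-", stamp)
  }
  if (!is.null(dir)) {
    name <- stamp
    i <- 1L
    while (file.exists(file.path(dir, name))) {
      i <- i + 1L
      name <- paste0(stamp, "-", i)
    }
    stamp <- name
  }
  stamp
}

#' Archive copy policy
#'
#' Decides whether a file accessed during the session is copied into the
#' archive. Files whose extension is listed in `do_not_archive` are never
#' copied, whatever their role. Input files larger than `maxsize_archive`
#' bytes are not copied (they remain listed in the manifest with
#' `skip_reason = "too_large"`). Outputs and code are copied regardless of
#' size, since they cannot be regenerated without rerunning the analysis.
#'
#' @param path File path (only the extension is consulted).
#' @param size File size in bytes.
#' @param role One of `"input"`, `"output"`, `"code"`.
#' @param config A [tracker_config()] object.
#' @return A list with elements `copy` (logical) and `skip_reason`
#'   (`NA_character_`, `"too_large"` or `"extension_excluded"`).
#' @examples
#' cfg <- tracker_config(maxsize_archive = 100)
#' should_copy("big.dat", size = 200, role = "input", cfg)
#' should_copy("big.dat", size = 200, role = "output", cfg)
#' @export
should_copy <- function(path, size, role, config) {
  stopifnot(is.numeric(size), length(size) == 1L, size >= 0)
  role <- match.arg(role, c("input", "output", "code"))
  ext <- tolower(tools::file_ext(path))
  excluded <- tolower(sub("^\\.", "", config$do_not_archive))
  if (nzchar(ext) && ext %in% excluded)
    return(list(copy = FALSE, skip_reason = "extension_excluded"))
  if (role == "input" && size > config$maxsize_archive)
    return(list(copy = FALSE, skip_reason = "too_large"))
  list(copy = TRUE, skip_reason = NA_character_)
}

#' MD5 checksum of a file
#'
#' @param path Path to an existing, readable file.
#' @return The 32-character lowercase hexadecimal MD5 digest of the file's
#'   bytes.
#' @export
compute_checksum <- function(path) {
  if (length(path) != 1L || !file.exists(path) ||
      isTRUE(file.info(path)$isdir))
    stop("cannot checksum '", path, "': no such file", call. = FALSE)
  md5 <- unname(tools::md5sum(path))
  if (is.na(md5))
    stop("cannot checksum '", path, "': file unreadable", call. = FALSE)
  tolower(md5)
}

# assign an archive-internal name, unique among `taken`; collisions get a
# deterministic "-2", "-3", ... inserted before the extension
.unique_archived_name <- function(base, taken) {
  if (!(base %in% taken)) return(base)
  ext <- tools::file_ext(base)
  stem <- if (nzchar(ext)) sub(paste0("\\.", ext, "$"), "", base) else base
  i <- 1L
  repeat {
    i <- i + 1L
    cand <- if (nzchar(ext)) paste0(stem, "-", i, ".", ext)
            else paste0(stem, "-", i)
    if (!(cand %in% taken)) return(cand)
  }
}

#' Materialise a session into a read-only, checksummed archive
#'
#' Creates the timestamped archive directory and fills it with: one copy of
#' every distinct file the session touched (de-duplicated across repeated
#' accesses; a file both written and read is archived once, in its final
#' state, with role `output`), subject to the [should_copy()] policy;
#' `APPENDIX.txt`, the human-readable rendering of all session details;
#' flat tab-separated exports of the file and random detail tables;
#' `MANIFEST.tsv`, the per-file size/MD5/mtime table; and, written last,
#' the serialized details document carrying the full manifest. The
#' directory is then locked read-only.
#'
#' Copies preserve content bytes and modification times. A recorded file
#' that no longer exists at archiving time yields a manifest entry with
#' `copied = FALSE` and `skip_reason = "vanished"` plus a warning.
#'
#' @param session An `rc_session` whose hooks have been removed and whose
#'   end time is set (normally called via [end_tracking()]).
#' @param config The session's [tracker_config()].
#' @param dir Parent directory for the archive.
#' @return An `rc_manifest` object: list with `entries` (data frame),
#'   `archive_path`, `created_at` and the serialized `details` document.
#' @export
build_archive <- function(session, config = session$config, dir = ".") {
  if (!inherits(session, "rc_session"))
    stop("'session' must be an rc_session handle", call. = FALSE)
  if (is.null(session$session_end))
    stop("session must be ended before archiving", call. = FALSE)
  if (!dir.exists(dir))
    stop("archive destination does not exist: ", dir, call. = FALSE)

  name <- archive_name(config$archive_folder, Sys.time(), dir = dir)
  archive <- file.path(dir, name)
  if (!dir.create(archive))
    stop("could not create archive directory: ", archive, call. = FALSE)

  script <- if (is.null(session$script_path)) "" else
    normalizePath(session$script_path, winslash = "/", mustWork = FALSE)
  paths <- sort(ls(envir = session$roles))
  reserved <- .reserved_names(config)
  taken <- reserved
  rows <- list()
  for (p in paths) {
    role <- get(p, envir = session$roles)
    if (identical(p, script)) role <- "code"
    aname <- .unique_archived_name(basename(p), taken)
    info <- file.info(p)
    if (is.na(info$size) || isTRUE(info$isdir)) {
      warning("recorded file vanished before archiving: ", p, call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        archived_name = aname, original_path = p, size = NA_real_,
        md5 = NA_character_, mtime = as.POSIXct(NA), role = role,
        copied = FALSE, skip_reason = "vanished",
        stringsAsFactors = FALSE)
      taken <- c(taken, aname)
      next
    }
    pol <- should_copy(p, info$size,
                       if (role == "code") "code" else role, config)
    if (pol$copy) {
      dest <- file.path(archive, aname)
      if (!file.copy(p, dest, overwrite = FALSE, copy.date = TRUE))
        stop("failed to copy '", p, "' into the archive", call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        archived_name = aname, original_path = p,
        size = file.info(dest)$size, md5 = compute_checksum(dest),
        mtime = file.info(dest)$mtime, role = role, copied = TRUE,
        skip_reason = NA_character_, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        archived_name = aname, original_path = p, size = info$size,
        md5 = NA_character_, mtime = info$mtime, role = role,
        copied = FALSE, skip_reason = pol$skip_reason,
        stringsAsFactors = FALSE)
    }
    taken <- c(taken, aname)
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(archived_name = character(), original_path = character(),
               size = numeric(), md5 = character(),
               mtime = as.POSIXct(character()), role = character(),
               copied = logical(), skip_reason = character(),
               stringsAsFactors = FALSE)

  created_at <- Sys.time()
  details <- structure(list(
    format_version = .details_format_version,
    package_version = as.character(utils::packageVersion("provtrack")),
    config = config,
    file_details = session$file_details,
    random_details = session$random_details,
    system_calls = session$system_calls,
    environment = session$environment,
    session_start = session$session_start,
    session_end = session$session_end,
    script_path = session$script_path,
    archive_path = archive,
    created_at = created_at,
    manifest = entries), class = "rc_details")

  # metadata files; each is checksummed into the manifest after writing
  add_meta <- function(entries, fname, writer) {
    dest <- file.path(archive, fname)
    writer(dest)
    rbind(entries, data.frame(
      archived_name = fname, original_path = dest,
      size = file.info(dest)$size, md5 = compute_checksum(dest),
      mtime = file.info(dest)$mtime, role = "details", copied = TRUE,
      skip_reason = NA_character_, stringsAsFactors = FALSE))
  }
  entries <- add_meta(entries, "APPENDIX.txt", function(dest)
    writeLines(render_appendix(details), dest))
  entries <- add_meta(entries, "rc.file.details.tsv", function(dest)
    .write_tsv(.abbrev_file_table(details), dest))
  entries <- add_meta(entries, "rc.random.details.tsv", function(dest)
    .write_tsv(.abbrev_random_table(details), dest))
  entries <- add_meta(entries, "MANIFEST.tsv", function(dest)
    .write_tsv(.manifest_table(entries), dest))

  details$manifest <- entries
  saveRDS(details, file.path(archive, config$details_file))
  set_read_only(archive)

  structure(list(entries = entries, archive_path = archive,
                 created_at = created_at, details = details),
            class = "rc_manifest")
}

.manifest_table <- function(entries) {
  out <- entries
  out$mtime <- format(out$mtime, "%Y-%m-%d %H:%M:%S")
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
}

#' Lock or unlock an archive
#'
#' `set_read_only()` removes write permission from every file in the
#' archive and from the directory itself, so the archived record cannot be
#' modified inadvertently. The protection is advisory — permissions can be
#' restored with `unlock_archive()` (or by anyone with sufficient
#' privilege), so deliberate modification remains possible and is exactly
#' what the audit tools detect.
#'
#' @param archive_path Path to an archive directory.
#' @return The path, invisibly.
#' @export
set_read_only <- function(archive_path) {
  if (!dir.exists(archive_path))
    stop("no such archive directory: ", archive_path, call. = FALSE)
  files <- list.files(archive_path, full.names = TRUE, recursive = TRUE)
  ok <- TRUE
  for (f in files) ok <- Sys.chmod(f, mode = "0444") && ok
  ok <- Sys.chmod(archive_path, mode = "0555") && ok
  if (!ok)
    warning("could not set read-only permissions on ", archive_path,
            call. = FALSE)
  invisible(archive_path)
}

#' @rdname set_read_only
#' @export
unlock_archive <- function(archive_path) {
  if (!dir.exists(archive_path))
    stop("no such archive directory: ", archive_path, call. = FALSE)
  Sys.chmod(archive_path, mode = "0755")
  for (f in list.files(archive_path, full.names = TRUE, recursive = TRUE))
    Sys.chmod(f, mode = "0644")
  invisible(archive_path)
}

#' Read a serialized details document
#'
#' @param path Either an archive directory (the details file is located
#'   inside it) or the path of a details file itself.
#' @return The `rc_details` document: config, detail records, environment
#'   snapshot, timestamps and the archive manifest.
#' @export
read_details <- function(path) {
  file <- path
  if (dir.exists(path)) {
    cand <- list.files(path, pattern = "\\.rds$", full.names = TRUE)
    pref <- cand[basename(cand) == "rc.details.rds"]
    file <- if (length(pref)) pref[1L] else cand[1L]
    if (is.null(file) || length(file) == 0L || is.na(file))
      stop("no details file found in archive: ", path, call. = FALSE)
  }
  if (!file.exists(file))
    stop("details file not found: ", file, call. = FALSE)
  details <- tryCatch(readRDS(file), error = function(e)
    stop("corrupt details file '", file, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(details) || is.null(details$format_version) ||
      is.null(details$manifest))
    stop("not a provenance details document: ", file, call. = FALSE)
  class(details) <- "rc_details"
  details
}

# ---- abbreviated tables (the compact views of the two detail objects) ------

.abbrev_file_table <- function(x) {
  df <- file_details(x)
  data.frame(top.call = df$top_call, mid.call = df$mid_call,
             bot.call = df$bot_call,
             call.time = format(df$call_time, "%a %b %e %H:%M:%S %Y"),
             description = basename(df$description),
             open = df$open, stringsAsFactors = FALSE)
}

.abbrev_random_table <- function(x) {
  df <- random_details(x)
  data.frame(top.call = df$top_call, mid.call = df$mid_call,
             bot.call = df$bot_call,
             call.date = format(df$call_time, "%b %e %H:%M:%S"),
             seed = ifelse(is.na(df$seed), "", as.character(df$seed)),
             kind = ifelse(is.na(df$kind), "", df$kind),
             normal.kind = ifelse(is.na(df$normal_kind), "",
                                  df$normal_kind),
             stringsAsFactors = FALSE)
}

# ---- appendix --------------------------------------------------------------

#' Render the plain-text appendix of a session
#'
#' Produces the human-readable account of a tracked session — environment
#' snapshot, file-access table, random-generation table, system calls and
#' the archive manifest — as a character vector of lines, suitable for
#' writing to a file or pasting into a literate-programming report. The
#' rendering depends only on the serialized details, so regenerating the
#' appendix from a reloaded details document reproduces it exactly.
#'
#' @param x An `rc_details` document (from [read_details()]) or an ended
#'   `rc_session`.
#' @param manifest Optional `rc_manifest`, required only when `x` is a
#'   session that has not been archived through [build_archive()].
#' @return Character vector of text lines.
#' @export
render_appendix <- function(x, manifest = NULL) {
  if (inherits(x, "rc_session")) {
    entries <- if (!is.null(manifest)) manifest$entries else
      data.frame()
    x <- list(file_details = x$file_details,
              random_details = x$random_details,
              system_calls = x$system_calls,
              environment = x$environment,
              session_start = x$session_start,
              session_end = x$session_end,
              archive_path = if (!is.null(manifest))
                manifest$archive_path else "",
              created_at = if (!is.null(manifest)) manifest$created_at
              else NULL,
              manifest = entries)
  }
  fmt <- function(t) if (is.null(t) || all(is.na(t))) "" else
    format(t, "%Y-%m-%d %H:%M:%S")
  rule <- function(title) c(
    paste0("---- ", title, " ",
           strrep("-", max(0L, 58L - nchar(title)))))
  tbl <- function(df) {
    if (!nrow(df)) return("  (none)")
    paste0("  ", utils::capture.output(print(df, right = FALSE)))
  }

  env <- x$environment
  out <- c("================================================================",
           " Reproducible computing appendix",
           "================================================================",
           paste0("Session started: ", fmt(x$session_start)),
           paste0("Session ended:   ", fmt(x$session_end)),
           paste0("Archive:         ", basename(x$archive_path)),
           "",
           rule("Environment"))
  if (!is.null(env)) {
    plat <- unlist(env$platform_info)
    out <- c(out,
             paste0("Interpreter:    ", env$interpreter_version),
             paste0("Platform:       ",
                    paste(names(plat), plat, sep = "=", collapse = " ")),
             paste0("Command args:   ",
                    paste(env$command_args, collapse = " ")),
             paste0("Memory in use:  ", format(env$memory_usage,
                                               scientific = FALSE),
                    " bytes"),
             "Loaded packages:",
             tbl(env$loaded_packages))
  } else {
    out <- c(out, "  (no snapshot)")
  }
  out <- c(out, "",
           rule("File access details"), tbl(.abbrev_file_table(x)), "",
           rule("Random number generation details"),
           tbl(.abbrev_random_table(x)), "",
           rule("System calls"),
           tbl(system_call_details(x)[, c("top_call", "mid_call",
                                          "bot_call", "command"),
                                      drop = FALSE]), "",
           rule("Archive manifest"))
  man <- x$manifest
  if (!is.null(man) && nrow(man)) {
    man <- man[man$role %in% c("code", "input", "output"), , drop = FALSE]
    out <- c(out, tbl(.manifest_table(man)))
  } else {
    out <- c(out, "  (none)")
  }
  out
}

#' @export
print.rc_manifest <- function(x, ...) {
  cat("<archive manifest> ", x$archive_path, "\n", sep = "")
  cat("  created: ", format(x$created_at), "\n", sep = "")
  roles <- table(x$entries$role)
  cat("  entries: ", nrow(x$entries), " (",
      paste(names(roles), roles, sep = ": ", collapse = ", "), ")\n",
      sep = "")
  n_skip <- sum(!x$entries$copied)
  if (n_skip) cat("  not copied: ", n_skip, "\n", sep = "")
  invisible(x)
}

#' @export
print.rc_details <- function(x, ...) {
  cat("<provenance details> format ", x$format_version, "\n", sep = "")
  cat("  session: ", format(x$session_start), " -> ",
      format(x$session_end), "\n", sep = "")
  cat("  archive: ", x$archive_path, "\n", sep = "")
  cat("  records: ", length(x$file_details), " file / ",
      length(x$random_details), " random / ",
      length(x$system_calls), " system\n", sep = "")
  invisible(x)
}
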
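# Shared per-entry audit: for each manifest entry that was copied, check
# existence, then size, then MD5, then modification time, reporting the
# first attribute that fails. An mtime change with matching MD5 is a
# metadata-severity discrepancy (the content claim still holds); all other
# kinds are content severity.
.mtime_tolerance <- 2  # seconds; survives coarse filesystem/zip stamps

.disc_row <- function(name, kind, expected = NA_character_,
                      observed = NA_character_,
                      severity = "content") {
  data.frame(archived_name = name, kind = kind, expected = expected,
             observed = observed, severity = severity,
             stringsAsFactors = FALSE)
}

.empty_discrepancies <- function()
  data.frame(archived_name = character(), kind = character(),
             expected = character(), observed = character(),
             severity = character(), stringsAsFactors = FALSE)

.audit_entries <- function(entries, probe) {
  rows <- list()
  checked <- 0L
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    if (!isTRUE(e$copied)) next
    checked <- checked + 1L
    obs <- probe(e$archived_name)
    if (is.null(obs)) {
      rows[[length(rows) + 1L]] <- .disc_row(e$archived_name, "missing")
      next
    }
    if (!is.na(obs$size) && obs$size != e$size) {
      rows[[length(rows) + 1L]] <- .disc_row(
        e$archived_name, "size_mismatch",
        expected = format(e$size, scientific = FALSE),
        observed = format(obs$size, scientific = FALSE))
      next
    }
    if (!is.na(obs$md5) && obs$md5 != e$md5) {
      rows[[length(rows) + 1L]] <- .disc_row(
        e$archived_name, "md5_mismatch", expected = e$md5,
        observed = obs$md5)
      next
    }
    if (!is.null(obs$mtime) && !is.na(obs$mtime) && !is.na(e$mtime) &&
        abs(as.numeric(obs$mtime) - as.numeric(e$mtime)) >
          .mtime_tolerance) {
      rows[[length(rows) + 1L]] <- .disc_row(
        e$archived_name, "mtime_mismatch",
        expected = format(e$mtime, "%Y-%m-%d %H:%M:%S"),
        observed = format(obs$mtime, "%Y-%m-%d %H:%M:%S"),
        severity = "metadata")
    }
  }
  list(discrepancies = if (length(rows)) do.call(rbind, rows) else
    .empty_discrepancies(), files_checked = checked)
}

.audit_report <- function(path, audit, extras) {
  disc <- audit$discrepancies
  if (length(extras))
    disc <- rbind(disc, do.call(rbind, lapply(extras, function(nm)
      .disc_row(nm, "extra_file", observed = nm))))
  structure(list(archive_path = path, checked_at = Sys.time(),
                 discrepancies = disc,
                 files_checked = audit$files_checked),
            class = "rc_audit_report")
}

#' Audit an archive against its recorded manifest
#'
#' Reads the manifest embedded in the archive's serialized details document
#' and verifies, for every file that was copied at archiving time, its
#' existence, size, MD5 checksum and modification time (in that order; the
#' first failing attribute is reported per file). Files present in the
#' directory but absent from the manifest are reported as `extra_file`;
#' this goes beyond the recorded-manifest audit and is an extension of the
#' original design. A fresh, untouched archive audits clean.
#'
#' @param archive_path Path to an archive directory.
#' @return An `rc_audit_report`: `archive_path`, `checked_at`,
#'   `discrepancies` (data frame with columns `archived_name`, `kind`,
#'   `expected`, `observed`, `severity`) and `files_checked`.
#' @seealso [compare_archives()], [check_zipfile()]
#' @export
check_archive <- function(archive_path) {
  if (!dir.exists(archive_path))
    stop("no such archive directory: ", archive_path, call. = FALSE)
  details <- read_details(archive_path)
  entries <- details$manifest
  probe <- function(name) {
    f <- file.path(archive_path, name)
    if (!file.exists(f)) return(NULL)
    info <- file.info(f)
    list(size = info$size, md5 = compute_checksum(f), mtime = info$mtime)
  }
  audit <- .audit_entries(entries, probe)
  present <- list.files(archive_path)
  known <- c(entries$archived_name, basename(details$config$details_file))
  .audit_report(archive_path, audit, setdiff(present, known))
}

#' Audit a zip archive against its embedded manifest
#'
#' Extracts the serialized details document from the zip and audits every
#' member recorded as copied, exactly as [check_archive()] does for a
#' directory: existence, size, MD5 and modification time (the latter with
#' a 2-second tolerance, matching the granularity of zip timestamps).
#'
#' @param zip_path Path to a zip file created by [create_zip_archive()].
#' @return An `rc_audit_report`.
#' @export
check_zipfile <- function(zip_path) {
  if (!file.exists(zip_path))
    stop("no such zip file: ", zip_path, call. = FALSE)
  listing <- .read_zip_directory(zip_path)
  rds <- listing$name[grepl("\\.rds$", listing$name)]
  if (!length(rds))
    stop("zip file has no embedded details document: ", zip_path,
         call. = FALSE)
  rds <- if ("rc.details.rds" %in% rds) "rc.details.rds" else rds[1L]
  tmp <- tempfile("provtrack-zip-")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(zip_path, files = rds, exdir = tmp)
  details <- read_details(file.path(tmp, rds))
  entries <- details$manifest
  probe <- function(name) {
    i <- match(name, listing$name)
    if (is.na(i)) return(NULL)
    utils::unzip(zip_path, files = name, exdir = tmp, overwrite = TRUE)
    list(size = listing$size[i],
         md5 = compute_checksum(file.path(tmp, name)),
         mtime = listing$mtime[i])
  }
  audit <- .audit_entries(entries, probe)
  known <- c(entries$archived_name, basename(details$config$details_file))
  .audit_report(zip_path, audit, setdiff(listing$name, known))
}

#' Compare two archives file by file
#'
#' Matches files of the two archive directories by name and compares the
#' size, MD5 checksum and modification time of each matched pair (every
#' differing attribute is reported); files present on only one side are
#' listed separately. Comparison keys on the archive-internal file name,
#' not the original path, so archives can be compared after moving between
#' machines.
#'
#' @param left_path,right_path Paths to two archive directories.
#' @return An `rc_comparison`: `left_path`, `right_path`,
#'   `common_mismatches` (discrepancy data frame; `expected` holds the
#'   left value, `observed` the right), `only_in_left`, `only_in_right`.
#' @export
compare_archives <- function(left_path, right_path) {
  for (p in c(left_path, right_path))
    if (!dir.exists(p))
      stop("no such archive directory: ", p, call. = FALSE)
  lf <- list.files(left_path)
  rf <- list.files(right_path)
  rows <- list()
  for (nm in sort(intersect(lf, rf))) {
    li <- file.info(file.path(left_path, nm))
    ri <- file.info(file.path(right_path, nm))
    if (li$size != ri$size)
      rows[[length(rows) + 1L]] <- .disc_row(
        nm, "size_mismatch",
        expected = format(li$size, scientific = FALSE),
        observed = format(ri$size, scientific = FALSE))
    lmd5 <- compute_checksum(file.path(left_path, nm))
    rmd5 <- compute_checksum(file.path(right_path, nm))
    if (lmd5 != rmd5)
      rows[[length(rows) + 1L]] <- .disc_row(nm, "md5_mismatch",
                                             expected = lmd5,
                                             observed = rmd5)
    if (abs(as.numeric(li$mtime) - as.numeric(ri$mtime)) >
        .mtime_tolerance)
      rows[[length(rows) + 1L]] <- .disc_row(
        nm, "mtime_mismatch",
        expected = format(li$mtime, "%Y-%m-%d %H:%M:%S"),
        observed = format(ri$mtime, "%Y-%m-%d %H:%M:%S"),
        severity = "metadata")
  }
  structure(list(left_path = left_path, right_path = right_path,
                 common_mismatches = if (length(rows)) do.call(rbind, rows)
                 else .empty_discrepancies(),
                 only_in_left = sort(setdiff(lf, rf)),
                 only_in_right = sort(setdiff(rf, lf))),
            class = "rc_comparison")
}

#' Number of discrepancies in an audit or comparison report
#' @param report An `rc_audit_report` or `rc_comparison`.
#' @return Integer count; zero means the archive(s) are unchanged/equal.
#' @export
n_discrepancies <- function(report) {
  if (inherits(report, "rc_audit_report"))
    return(nrow(report$discrepancies))
  if (inherits(report, "rc_comparison"))
    return(nrow(report$common_mismatches) + length(report$only_in_left) +
             length(report$only_in_right))
  stop("not an audit or comparison report", call. = FALSE)
}

#' @export
print.rc_audit_report <- function(x, ...) {
  cat("<archive audit> ", x$archive_path, "\n", sep = "")
  cat("  files checked: ", x$files_checked, "\n", sep = "")
  d <- x$discrepancies
  if (!nrow(d)) {
    cat("  no discrepancies: archive matches its manifest\n")
  } else {
    cat("  discrepancies: ", nrow(d),
        " (", sum(d$severity == "content"), " content, ",
        sum(d$severity == "metadata"), " metadata)\n", sep = "")
    print(d, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.rc_comparison <- function(x, ...) {
  cat("<archive comparison>\n")
  cat("  left:  ", x$left_path, "\n", sep = "")
  cat("  right: ", x$right_path, "\n", sep = "")
  if (n_discrepancies(x) == 0L) {
    cat("  archives are equivalent\n")
    return(invisible(x))
  }
  if (nrow(x$common_mismatches)) {
    cat("  mismatched files:\n")
    print(x$common_mismatches, row.names = FALSE)
  }
  if (length(x$only_in_left))
    cat("  only in left: ", paste(x$only_in_left, collapse = ", "), "\n")
  if (length(x$only_in_right))
    cat("  only in right:", paste(x$only_in_right, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.rc_audit_report <- function(x, ...) x$discrepancies

#' @export
as.data.frame.rc_comparison <- function(x, ...) {
  extra <- rbind(
    if (length(x$only_in_left)) do.call(rbind, lapply(
      x$only_in_left, function(nm) .disc_row(nm, "extra_file",
                                             expected = nm))),
    if (length(x$only_in_right)) do.call(rbind, lapply(
      x$only_in_right, function(nm) .disc_row(nm, "extra_file",
                                              observed = nm))))
  rbind(x$common_mismatches, extra)
}
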
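# Shared fixtures and independent oracles for the suite. All fixtures are
# generated in code under tempdir(); nothing is read from disk.

fixture_dir <- function(prefix = "fx-") {
  d <- tempfile(prefix)
  dir.create(d)
  d
}

# Run a generated workload under tracking and hand back everything the
# assertions need. Archives land inside the workload directory.
track_workload <- function(workload, config = tracker_config()) {
  archive <- run_tracked(workload$script, config)
  details <- read_details(archive)
  list(archive = archive, details = details,
       manifest = attr(archive, "manifest"))
}

# Independent MD5 oracle (Python hashlib), used to cross-check the
# package's checksums.
python_md5 <- function(path) {
  out <- system2("python",
                 c("-c",
                   shQuote(paste0(
                     "import hashlib,sys;",
                     "print(hashlib.md5(open(sys.argv[1],'rb')",
                     ".read()).hexdigest())")),
                   shQuote(path)),
                 stdout = TRUE)
  trimws(out[length(out)])
}

has_python <- function() nzchar(Sys.which("python"))

# Naive byte-by-byte directory diff: the oracle compare_archives must
# agree with about which files differ or are unmatched.
dir_byte_diff <- function(left, right) {
  lf <- list.files(left)
  rf <- list.files(right)
  common <- intersect(lf, rf)
  differing <- Filter(function(nm) {
    a <- readBin(file.path(left, nm), "raw",
                 n = file.info(file.path(left, nm))$size)
    b <- readBin(file.path(right, nm), "raw",
                 n = file.info(file.path(right, nm))$size)
    !identical(a, b)
  }, common)
  list(differing = sort(unlist(differing, use.names = FALSE)),
       only_in_left = sort(setdiff(lf, rf)),
       only_in_right = sort(setdiff(rf, lf)))
}

# Writable clone of a (read-only) archive, mtimes preserved so that only
# deliberate mutations show up in audits.
clone_archive <- function(archive, dest = tempfile("clone-")) {
  dir.create(dest)
  for (f in list.files(archive, full.names = TRUE))
    file.copy(f, file.path(dest, basename(f)), copy.date = TRUE)
  Sys.chmod(list.files(dest, full.names = TRUE), "0644")
  dest
}

flip_one_byte <- function(path) {
  size <- file.info(path)$size
  stopifnot(size > 0)
  bytes <- readBin(path, "raw", n = size)
  mt <- file.info(path)$mtime
  bytes[1L] <- xor(bytes[1L], as.raw(0xff))
  writeBin(bytes, path)
  Sys.setFileTime(path, mt)  # isolate the content change from mtime noise
  invisible(path)
}

read_bytes <- function(path)
  readBin(path, "raw", n = file.info(path)$size)
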
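# Archive construction: naming, copy policy, checksums, manifest
# completeness, read-only locking, details round trip.

test_that("archive names follow the timestamped forms", {
  ts <- as.POSIXct("2014-03-27 14:52:14")
  expect_equal(archive_name("mydir", ts), "mydir-2014-03-27-14-52-14")
  expect_equal(archive_name(NULL, ts), "2014-03-27-14-52-14")
  expect_error(archive_name("a/b", ts), "separator")

  d <- fixture_dir()
  dir.create(file.path(d, "mydir-2014-03-27-14-52-14"))
  expect_equal(archive_name("mydir", ts, dir = d),
               "mydir-2014-03-27-14-52-14-2")
  dir.create(file.path(d, "mydir-2014-03-27-14-52-14-2"))
  expect_equal(archive_name("mydir", ts, dir = d),
               "mydir-2014-03-27-14-52-14-3")
})

test_that("copy policy: size cap on inputs only, extensions on all roles", {
  cfg <- tracker_config(maxsize_archive = 100,
                        do_not_archive = c(".CEL"))
  expect_equal(should_copy("x.dat", 200, "input", cfg),
               list(copy = FALSE, skip_reason = "too_large"))
  expect_equal(should_copy("x.dat", 100, "input", cfg)$copy, TRUE)
  expect_equal(should_copy("x.dat", 1e9, "output", cfg)$copy, TRUE)
  expect_equal(should_copy("x.CEL", 10, "input", cfg),
               list(copy = FALSE, skip_reason = "extension_excluded"))
  # extension matching is case-insensitive and applies to outputs too
  expect_equal(should_copy("x.cel", 10, "output", cfg)$skip_reason,
               "extension_excluded")
  expect_equal(should_copy("x.dat", 10, "code", cfg)$copy, TRUE)
})

test_that("checksums are 32-hex MD5 digests agreeing with an oracle", {
  d <- fixture_dir()
  empty <- file.path(d, "empty.bin")
  file.create(empty)
  expect_equal(compute_checksum(empty),
               "d41d8cd98f00b204e9800998ecf8427e")
  abc <- file.path(d, "abc.txt")
  writeBin(charToRaw("abc"), abc)
  expect_equal(compute_checksum(abc),
               "900150983cd24fb0d6963f7d28e17f72")
  set.seed(5)
  blob <- file.path(d, "blob.bin")
  writeBin(as.raw(sample.int(256, 4096, replace = TRUE) - 1L), blob)
  md5 <- compute_checksum(blob)
  expect_match(md5, "^[0-9a-f]{32}$")
  if (has_python()) expect_equal(md5, python_md5(blob))
  expect_error(compute_checksum(file.path(d, "nope.bin")), "nope.bin")
})

test_that("the worked-example archive has one entry per distinct path", {
  wl <- make_worked_example(fixture_dir(), n_points = 20)
  res <- track_workload(wl)
  man <- res$manifest$entries
  user <- man[man$role != "details", ]
  # tabular file accessed twice (write then read) appears exactly once,
  # as an output; script is code; image is output
  expect_equal(sort(user$archived_name),
               sort(c("my.program.R", wl$expected$outputs)))
  expect_equal(user$role[user$archived_name == "my.program.R"], "code")
  expect_setequal(user$role[user$archived_name %in% wl$expected$outputs],
                  "output")
  expect_equal(sum(user$archived_name == "pt.data.txt"), 1L)
  # copies preserve bytes and checksums verify immediately after build
  for (i in seq_len(nrow(man))[man$copied]) {
    f <- file.path(res$archive, man$archived_name[i])
    expect_equal(compute_checksum(f), man$md5[i])
  }
  # copies preserve modification times
  pt <- file.path(wl$dir, "pt.data.txt")
  expect_lt(abs(as.numeric(file.info(pt)$mtime) -
                as.numeric(man$mtime[man$archived_name == "pt.data.txt"])),
            2)
})

test_that("identical base names from different directories stay distinct", {
  d <- fixture_dir()
  dir.create(file.path(d, "a"))
  dir.create(file.path(d, "b"))
  writeLines("first", file.path(d, "a", "data.txt"))
  writeLines("second", file.path(d, "b", "data.txt"))
  script <- file.path(d, "collide.R")
  writeLines(c('x <- readLines("a/data.txt")',
               'y <- readLines("b/data.txt")'), script)
  res <- track_workload(list(script = script, dir = d))
  man <- res$manifest$entries
  inputs <- man[man$role == "input", ]
  expect_equal(nrow(inputs), 2L)
  expect_equal(anyDuplicated(man$archived_name), 0L)
  expect_setequal(basename(inputs$original_path), "data.txt")
  # both contents preserved under their distinct names
  contents <- sort(unname(vapply(
    file.path(res$archive, inputs$archived_name), readLines,
    character(1L))))
  expect_equal(contents, c("first", "second"))
})

test_that("size and extension policies shape the manifest", {
  d <- fixture_dir()
  wl <- make_stress_workload(d, n_inputs = 3L,
                             input_sizes = c(50L, 5000L, 50L),
                             input_extensions = c("dat", "dat", "cel"),
                             n_outputs = 1L, output_sizes = 5000L,
                             seed = 3L)
  cfg <- tracker_config(maxsize_archive = 1000,
                        do_not_archive = "cel")
  res <- track_workload(wl, cfg)
  man <- res$manifest$entries
  get1 <- function(nm) man[man$archived_name == nm, ]
  expect_true(get1("input-01.dat")$copied)
  big <- get1("input-02.dat")
  expect_false(big$copied)
  expect_equal(big$skip_reason, "too_large")
  expect_false(file.exists(file.path(res$archive, "input-02.dat")))
  cel <- get1("input-03.cel")
  expect_false(cel$copied)
  expect_equal(cel$skip_reason, "extension_excluded")
  # the 5 KB output exceeds maxsize but is copied regardless of size
  expect_true(get1("output-01.txt")$copied)
  # no copied input exceeds the cap
  ins <- man[man$role == "input" & man$copied, ]
  expect_true(all(ins$size <= 1000))
  # uncopied entries still carry size and mtime of the original
  expect_equal(big$size, 5000)
})

test_that("a vanished input is flagged, not fatal", {
  d <- fixture_dir()
  doomed <- file.path(d, "doomed.txt")
  writeLines("here today", doomed)
  script <- file.path(d, "vanish.R")
  writeLines(c('invisible(readLines("doomed.txt"))',
               'file.remove("doomed.txt")'), script)
  expect_warning(res <- track_workload(list(script = script, dir = d)),
                 "vanished")
  e <- res$manifest$entries
  row <- e[e$archived_name == "doomed.txt", ]
  expect_false(row$copied)
  expect_equal(row$skip_reason, "vanished")
})

test_that("archives are locked read-only and can be unlocked", {
  wl <- make_stress_workload(fixture_dir(), n_inputs = 1L, n_outputs = 1L,
                             seed = 8L)
  res <- track_workload(wl)
  mode_of <- function(f) as.character(file.mode(f))
  expect_equal(mode_of(res$archive), "555")
  for (f in list.files(res$archive, full.names = TRUE))
    expect_equal(mode_of(f), "444")
  unlock_archive(res$archive)
  expect_equal(mode_of(res$archive), "755")
  target <- file.path(res$archive, "input-01.dat")
  expect_silent(writeBin(as.raw(1:3), target))  # writable again
})

test_that("details round-trip and the appendix regenerates identically", {
  wl <- make_worked_example(fixture_dir(), n_points = 15)
  res <- track_workload(wl)
  on_disk <- readLines(file.path(res$archive, "APPENDIX.txt"))
  reloaded <- read_details(res$archive)
  expect_equal(reloaded$format_version, "1.0")
  expect_identical(render_appendix(reloaded), on_disk)
  expect_true(any(grepl("Interpreter:", on_disk)))
  # one appendix line per file-access record
  fd <- file_details(reloaded)
  tbl <- grep("\\bfile\\b|\\bjpeg\\b|\\bpng\\b", on_disk, value = TRUE)
  expect_gte(length(tbl), nrow(fd))

  # flat exports carry the canonical abbreviated headers
  fh <- readLines(file.path(res$archive, "rc.file.details.tsv"), n = 1L)
  expect_equal(strsplit(fh, "\t")[[1L]],
               c("top.call", "mid.call", "bot.call", "call.time",
                 "description", "open"))
  rh <- readLines(file.path(res$archive, "rc.random.details.tsv"), n = 1L)
  expect_equal(strsplit(rh, "\t")[[1L]],
               c("top.call", "mid.call", "bot.call", "call.date",
                 "seed", "kind", "normal.kind"))
})

test_that("an empty session still archives details and environment", {
  d <- fixture_dir()
  begin_tracking()
  a <- end_tracking(dir = d)
  expect_true(file.exists(file.path(a, "rc.details.rds")))
  det <- read_details(a)
  expect_equal(nrow(file_details(det)), 0L)
  expect_match(det$environment$interpreter_version, "^R version")
  expect_true(length(det$environment$platform_info) > 0)
  app <- render_appendix(det)
  expect_true(any(grepl("Interpreter:", app)))
})
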
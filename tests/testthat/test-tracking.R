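# Core session behaviour: seeding, interception, suppression policies,
# ordering, and clean teardown.

test_that("call-stack sketch keeps outermost, caller-of-bottom, bottom", {
  expect_equal(unname(sketch_call_stack(c("Sweave", "source", "file"))),
               c("Sweave", "source", "file"))
  expect_equal(unname(sketch_call_stack("begin_tracking")),
               rep("begin_tracking", 3L))
  expect_equal(unname(sketch_call_stack(c("a", "b"))), c("a", "a", "b"))
  # the middle element is the immediate caller of the intercepted call
  expect_equal(unname(sketch_call_stack(c("a", "b", "c", "d", "e"))),
               c("a", "d", "e"))
  expect_error(sketch_call_stack(character()), "non-empty")
})

test_that("sessions seed the generator and record the initialization event", {
  d <- fixture_dir()
  begin_tracking()
  rd <- random_details(read_details(end_tracking(dir = d)))
  expect_equal(rd$seed[1L], 123456789L)
  expect_equal(rd$kind[1L], "Mersenne-Twister")

  begin_tracking(tracker_config(rng_init = list(seed = 42)))
  rd <- random_details(read_details(end_tracking(dir = d)))
  expect_equal(rd$seed[1L], 42L)
  # generation events (none here) would leave seed empty; init never does
  expect_equal(nrow(rd), 1L)
})

test_that("nested sessions are rejected and ending without one errors", {
  d <- fixture_dir()
  begin_tracking()
  expect_error(begin_tracking(), "already active")
  end_tracking(dir = d)
  expect_error(end_tracking(dir = d), "no tracking session")
  expect_false(tracking_active())
})

test_that("file events are suppressed per policy, recorded otherwise", {
  d <- fixture_dir()
  pt <- file.path(d, "pt.data.txt")
  writeLines("x\ty", pt)
  begin_tracking(tracker_config(
    skip_file_calls = c("library", "my.loader"),
    skip_empty_description = TRUE))
  on.exit(if (tracking_active()) end_tracking(dir = d))

  r1 <- record_file_access(pt, "w",
                           c("Sweave", "write.table", "file"))
  expect_equal(r1$open, "w")
  expect_equal(r1$bot_call, "file")
  # empty description suppressed
  expect_null(record_file_access("", "r", c("toplevel", "file")))
  # any frame matching skip_file_calls suppresses
  expect_null(record_file_access("pkg/DESCRIPTION", "r",
                                 c("my.loader", "readLines", "file")))
  a <- end_tracking(dir = d)
  fd <- file_details(read_details(a))
  expect_equal(nrow(fd), 1L)
  expect_equal(basename(fd$description), "pt.data.txt")
})

test_that("write-like modes mark outputs, read-like mark inputs", {
  d <- fixture_dir()
  f_in <- file.path(d, "in.txt")
  f_out <- file.path(d, "out.txt")
  writeLines("x", f_in)
  begin_tracking()
  record_file_access(f_in, "r", "reader")
  record_file_access(f_out, "w", "writer")
  writeLines("y", f_out)
  a <- end_tracking(dir = d)
  man <- attr(a, "manifest")$entries
  expect_equal(man$role[man$archived_name == "in.txt"], "input")
  expect_equal(man$role[man$archived_name == "out.txt"], "output")
})

test_that("rng events respect the trace flag and the monitored set", {
  d <- fixture_dir()
  begin_tracking(tracker_config(rng_functions = c("runif", "rnorm")))
  record_random_event("runif", c("toplevel", "runif"))
  record_random_event("runif", c("toplevel", "runif"))
  expect_null(record_random_event("rbeta", c("toplevel", "rbeta")))
  a <- end_tracking(dir = d)
  rd <- random_details(read_details(a))
  expect_equal(nrow(rd), 3L)  # init + two draws
  expect_true(all(is.na(rd$seed[-1L])))

  begin_tracking(tracker_config(rng_trace = FALSE))
  for (i in 1:10) invisible(runif(1))
  a <- end_tracking(dir = d)
  expect_equal(nrow(random_details(read_details(a))), 1L)
})

test_that("system calls are stored verbatim in invocation order", {
  d <- fixture_dir()
  begin_tracking()
  record_system_call("echo hi", c("toplevel", "system"))
  record_system_call("plink --bfile x", c("toplevel", "system"))
  expect_error(record_system_call("", "system"), "non-empty")
  a <- end_tracking(dir = d)
  sc <- system_call_details(read_details(a))
  expect_equal(sc$command, c("echo hi", "plink --bfile x"))

  begin_tracking()
  a <- end_tracking(dir = d)
  expect_equal(nrow(system_call_details(read_details(a))), 0L)
})

test_that("record timestamps are non-decreasing within each list", {
  wl <- make_stress_workload(fixture_dir(), n_inputs = 4L, n_outputs = 3L,
                             n_rng_calls = 5L, seed = 11L)
  res <- track_workload(wl)
  for (df in list(file_details(res$details),
                  random_details(res$details))) {
    t <- as.numeric(df$call_time)
    expect_true(all(diff(t) >= 0))
  }
})

test_that("interception is fully removed at session end", {
  d <- fixture_dir()
  begin_tracking()
  a <- end_tracking(dir = d)
  # no wrapped functions remain
  expect_false(inherits(base::file, "functionWithTrace"))
  expect_false(inherits(stats::rnorm, "functionWithTrace"))
  # subsequent file and RNG activity creates no records anywhere
  f <- file.path(d, "after.txt")
  write.table(data.frame(x = 1), f)
  invisible(rnorm(3))
  det <- read_details(a)
  expect_false("after.txt" %in% basename(file_details(det)$description))
  expect_equal(nrow(random_details(det)), 1L)
  expect_false(tracking_active())
})

test_that("tracking is transparent: workload outputs identical on vs off", {
  wl <- make_worked_example(fixture_dir(), n_points = 40)
  res <- track_workload(wl, tracker_config(rng_init = list(seed = 99)))
  tracked <- lapply(file.path(wl$dir, wl$expected$outputs), read_bytes)

  # untracked run of the same script with the same seed
  d2 <- fixture_dir()
  wl2 <- make_worked_example(d2, n_points = 40)
  old <- setwd(d2)
  on.exit(setwd(old))
  set.seed(99)
  source(wl2$script, local = new.env(parent = globalenv()),
         keep.source = FALSE)
  setwd(old)
  untracked <- lapply(file.path(d2, wl2$expected$outputs), read_bytes)
  expect_identical(tracked, untracked)
})

test_that("equal seeds replay byte-identical random-dependent outputs", {
  runs <- lapply(1:2, function(i) {
    wl <- make_worked_example(fixture_dir(), n_points = 30)
    track_workload(wl, tracker_config(rng_init = list(seed = 2718)))
    lapply(file.path(wl$dir, wl$expected$outputs), read_bytes)
  })
  expect_identical(runs[[1L]], runs[[2L]])
})
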
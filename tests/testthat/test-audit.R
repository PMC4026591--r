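# Audit soundness: a discrepancy is reported iff the corresponding
# attribute actually changed, verified with single-mutation fixtures, and
# archive comparison agrees with a byte-by-byte oracle.

build_audit_fixture <- function(seed = 21L) {
  wl <- make_stress_workload(fixture_dir(), n_inputs = 3L, n_outputs = 2L,
                             input_sizes = c(64L, 128L, 256L),
                             n_rng_calls = 1L, seed = seed)
  track_workload(wl)
}

test_that("a fresh archive audits clean", {
  res <- build_audit_fixture()
  rep <- check_archive(res$archive)
  expect_equal(n_discrepancies(rep), 0L)
  expect_gt(rep$files_checked, 0L)
})

test_that("each single mutation yields exactly its own discrepancy", {
  res <- build_audit_fixture()
  target <- "input-02.dat"

  mutate_and_audit <- function(mutation) {
    clone <- clone_archive(res$archive)
    mutation(file.path(clone, target))
    check_archive(clone)
  }

  # delete -> missing
  rep <- mutate_and_audit(function(f) file.remove(f))
  expect_equal(nrow(rep$discrepancies), 1L)
  expect_equal(rep$discrepancies$kind, "missing")
  expect_equal(rep$discrepancies$archived_name, target)

  # truncate -> size_mismatch
  rep <- mutate_and_audit(function(f) {
    mt <- file.info(f)$mtime
    writeBin(read_bytes(f)[1:10], f)
    Sys.setFileTime(f, mt)
  })
  expect_equal(nrow(rep$discrepancies), 1L)
  expect_equal(rep$discrepancies$kind, "size_mismatch")

  # same-size byte flip -> md5_mismatch only
  rep <- mutate_and_audit(flip_one_byte)
  expect_equal(nrow(rep$discrepancies), 1L)
  expect_equal(rep$discrepancies$kind, "md5_mismatch")
  expect_equal(rep$discrepancies$archived_name, target)

  # touch -> mtime_mismatch, low severity (content claim intact)
  rep <- mutate_and_audit(function(f)
    Sys.setFileTime(f, file.info(f)$mtime + 30))
  expect_equal(nrow(rep$discrepancies), 1L)
  expect_equal(rep$discrepancies$kind, "mtime_mismatch")
  expect_equal(rep$discrepancies$severity, "metadata")

  # append -> size change
  rep <- mutate_and_audit(function(f) {
    con <- base::file(f, "ab")
    writeBin(as.raw(0L), con)
    close(con)
  })
  expect_equal(rep$discrepancies$kind, "size_mismatch")
})

test_that("files not in the manifest are reported as extra", {
  res <- build_audit_fixture()
  clone <- clone_archive(res$archive)
  writeLines("stray", file.path(clone, "stray.txt"))
  rep <- check_archive(clone)
  expect_equal(rep$discrepancies$kind, "extra_file")
  expect_equal(rep$discrepancies$observed, "stray.txt")
})

test_that("a missing or corrupt manifest is an error", {
  res <- build_audit_fixture()
  clone <- clone_archive(res$archive)
  file.remove(file.path(clone, "rc.details.rds"))
  expect_error(check_archive(clone), "details")
  writeLines("garbage", file.path(clone, "rc.details.rds"))
  expect_error(check_archive(clone), "corrupt|details")
})

test_that("an archive compared with itself is equivalent", {
  res <- build_audit_fixture()
  cmp <- compare_archives(res$archive, res$archive)
  expect_equal(n_discrepancies(cmp), 0L)
  expect_length(cmp$only_in_left, 0L)
  expect_length(cmp$only_in_right, 0L)
})

test_that("comparison finds unmatched files and attribute mismatches", {
  res <- build_audit_fixture()
  left <- clone_archive(res$archive)
  right <- clone_archive(res$archive)
  writeLines("extra", file.path(right, "extra.log"))
  cmp <- compare_archives(left, right)
  expect_equal(cmp$only_in_right, "extra.log")
  expect_length(cmp$only_in_left, 0L)
  expect_equal(nrow(cmp$common_mismatches), 0L)

  # same name, different content, same size -> md5 mismatch only
  flip_one_byte(file.path(right, "input-01.dat"))
  cmp <- compare_archives(left, right)
  m <- cmp$common_mismatches
  expect_equal(m$kind[m$archived_name == "input-01.dat"], "md5_mismatch")

  # size change reports both size and md5
  mt <- file.info(file.path(right, "input-03.dat"))$mtime
  writeBin(as.raw(1:8), file.path(right, "input-03.dat"))
  Sys.setFileTime(file.path(right, "input-03.dat"), mt)
  cmp <- compare_archives(left, right)
  kinds <- cmp$common_mismatches$kind[
    cmp$common_mismatches$archived_name == "input-03.dat"]
  expect_setequal(kinds, c("size_mismatch", "md5_mismatch"))
})

test_that("comparison is symmetric and agrees with a byte-diff oracle", {
  res <- build_audit_fixture()
  left <- clone_archive(res$archive)
  right <- clone_archive(res$archive)
  flip_one_byte(file.path(right, "input-02.dat"))
  writeLines("only right", file.path(right, "rightonly.txt"))
  file.remove(file.path(right, "output-01.txt"))

  ab <- compare_archives(left, right)
  ba <- compare_archives(right, left)
  expect_equal(ab$only_in_left, ba$only_in_right)
  expect_equal(ab$only_in_right, ba$only_in_left)
  expect_setequal(ab$common_mismatches$archived_name,
                  ba$common_mismatches$archived_name)

  oracle <- dir_byte_diff(left, right)
  content <- ab$common_mismatches[
    ab$common_mismatches$kind %in% c("size_mismatch", "md5_mismatch"), ]
  expect_equal(sort(unique(content$archived_name)), oracle$differing)
  expect_equal(ab$only_in_left, oracle$only_in_left)
  expect_equal(ab$only_in_right, oracle$only_in_right)

  # disjointness of the three report lists
  expect_length(intersect(ab$common_mismatches$archived_name,
                          c(ab$only_in_left, ab$only_in_right)), 0L)
})
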
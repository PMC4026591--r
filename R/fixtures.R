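# Self-contained test workloads with footprints known in advance, so the
# tracker's completeness can be verified against pure arithmetic rather
# than against itself.

#' Generate the worked-example workload
#'
#' Writes a small, self-contained analysis script that exercises each
#' monitored pathway once: it draws two random normal samples, writes them
#' to a tab-separated table, reads that table back, and renders a
#' scatterplot to an image file through a file-producing graphics device.
#' Run under tracking (via [run_tracked()]), its footprint is exactly four
#' file-access records — the script read, the tabular write, the tabular
#' read-back and the image write — and three random-event records — the
#' seed initialization plus the two draws. The footprint is independent of
#' `n_points`.
#'
#' @param dir Directory in which to place the script (created if needed);
#'   outputs land in the working directory of the tracked run.
#' @param n_points Number of points per sample.
#' @param device Graphics device: `"jpeg"`, `"png"`, or `"auto"` (jpeg
#'   when the build supports it, else png). The tracker records the file
#'   event, so the pixel content is irrelevant.
#' @return A list: `script` (path), `dir`, and `expected`, the
#'   independently known footprint (`n_file_events`, `n_random_events`,
#'   `n_system_calls`, `n_rng_draws`, `outputs`).
#' @examples
#' wl <- make_worked_example(tempfile("ex-"), n_points = 10)
#' readLines(wl$script)
#' @export
make_worked_example <- function(dir, n_points = 100,
                                device = c("auto", "jpeg", "png")) {
  device <- match.arg(device)
  if (device == "auto")
    device <- if (isTRUE(unname(capabilities("jpeg")))) "jpeg" else "png"
  stopifnot(is.numeric(n_points), length(n_points) == 1L, n_points >= 0)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory: ", dir, call. = FALSE)
  img <- paste0("scatterplot.", if (device == "jpeg") "jpg" else "png")
  lines <- c(
    "# simulate two normal samples, round-trip them through a table,",
    "# and draw a scatterplot",
    sprintf("x <- rnorm(%d)", n_points),
    sprintf("y <- rnorm(%d)", n_points),
    "pt.data <- data.frame(x = x, y = y)",
    'write.table(pt.data, "pt.data.txt", sep = "\\t", quote = FALSE,',
    "            row.names = FALSE)",
    'pt.data <- read.table("pt.data.txt", header = TRUE, sep = "\\t")',
    sprintf('%s("%s")', device, img),
    "if (nrow(pt.data) > 0) {",
    '  plot(pt.data$x, pt.data$y, xlab = "x", ylab = "y")',
    "} else {",
    "  plot.new()",
    "}",
    "invisible(dev.off())")
  script <- file.path(dir, "my.program.R")
  writeLines(lines, script)
  list(script = script, dir = dir,
       expected = list(n_file_events = 4L,   # script, write, read, image
                       n_random_events = 3L, # init + two draws
                       n_rng_draws = 2L,
                       n_system_calls = 0L,
                       outputs = c("pt.data.txt", img)))
}

#' Generate a parameterised stress workload
#'
#' Creates `n_inputs` input files of requested sizes and extensions (bytes
#' drawn reproducibly from `seed`), plus a script that reads each input
#' exactly once, writes `n_outputs` output files exactly once, performs
#' `n_rng_calls` uniform draws and issues `n_system_calls` trivial system
#' calls. The expected tracking footprint and the expected archive
#' manifest under any configuration are pure arithmetic on these
#' parameters — see `expected` and [expected_manifest()] — which is what
#' makes the workload usable as an oracle for policy and audit tests.
#'
#' @param dir Directory for inputs and script.
#' @param n_inputs,n_outputs,n_rng_calls,n_system_calls Non-negative
#'   counts.
#' @param input_sizes Sizes in bytes of the input files (recycled).
#' @param input_extensions Extensions of the input files (recycled,
#'   without dot).
#' @param output_sizes Approximate sizes of the output text files
#'   (recycled).
#' @param output_extensions Extensions of the output files (recycled).
#' @param seed Integer seed for the generated input bytes; the same seed
#'   reproduces identical files.
#' @return A list: `script`, `dir`, `inputs` (data frame with `name`,
#'   `path`, `size`), `outputs` (names), and `expected` footprint counts.
#' @export
make_stress_workload <- function(dir, n_inputs = 3L, n_outputs = 2L,
                                 input_sizes = 256L,
                                 input_extensions = "dat",
                                 output_sizes = 64L,
                                 output_extensions = "txt",
                                 n_rng_calls = 2L, n_system_calls = 0L,
                                 seed = 1L) {
  stopifnot(n_inputs >= 0, n_outputs >= 0, n_rng_calls >= 0,
            n_system_calls >= 0, all(input_sizes >= 0),
            all(output_sizes >= 0))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory: ", dir, call. = FALSE)
  set.seed(seed)
  sizes <- if (n_inputs) rep_len(input_sizes, n_inputs) else integer()
  iext <- if (n_inputs) rep_len(sub("^\\.", "", input_extensions),
                                n_inputs) else character()
  in_names <- if (n_inputs)
    sprintf("input-%02d.%s", seq_len(n_inputs), iext) else character()
  for (i in seq_len(n_inputs)) {
    bytes <- as.raw(sample.int(256L, sizes[i], replace = TRUE) - 1L)
    writeBin(bytes, file.path(dir, in_names[i]))
  }
  osizes <- if (n_outputs) rep_len(output_sizes, n_outputs) else integer()
  oext <- if (n_outputs) rep_len(sub("^\\.", "", output_extensions),
                                 n_outputs) else character()
  out_names <- if (n_outputs)
    sprintf("output-%02d.%s", seq_len(n_outputs), oext) else character()

  lines <- character()
  for (i in seq_len(n_inputs))
    lines <- c(lines,
               sprintf('con <- file("%s", "rb")', in_names[i]),
               sprintf('invisible(readBin(con, "raw", n = %d))', sizes[i]),
               "close(con)")
  for (i in seq_len(n_outputs))
    lines <- c(lines,
               sprintf('writeLines(strrep("x", %d), "%s")',
                       max(osizes[i] - 1L, 0L), out_names[i]))
  for (i in seq_len(n_rng_calls))
    lines <- c(lines, "invisible(runif(1))")
  for (i in seq_len(n_system_calls))
    lines <- c(lines,
               'invisible(system("true", ignore.stdout = TRUE,',
               "                 ignore.stderr = TRUE))")
  if (!length(lines)) lines <- "invisible(NULL)"
  script <- file.path(dir, "stress.R")
  writeLines(lines, script)

  list(script = script, dir = dir,
       inputs = data.frame(name = in_names,
                           path = file.path(dir, in_names),
                           size = as.numeric(sizes),
                           stringsAsFactors = FALSE),
       outputs = out_names,
       expected = list(
         n_file_events = 1L + n_inputs + n_outputs,
         n_random_events = 1L + n_rng_calls,
         n_rng_draws = as.integer(n_rng_calls),
         n_system_calls = as.integer(n_system_calls)))
}

#' Expected archive manifest of a stress workload
#'
#' Applies the [should_copy()] policy to the known file set of a
#' [make_stress_workload()] fixture, without running the tracker: the
#' script has role `code`, every input its known size and role `input`,
#' every output role `output` (size irrelevant to the policy). The result
#' predicts, for any configuration, which manifest entries a tracked run
#' must produce and which of them are copied.
#'
#' @param workload The list returned by [make_stress_workload()].
#' @param config A [tracker_config()].
#' @return Data frame with columns `archived_name`, `role`, `copied`,
#'   `skip_reason`, sorted by `archived_name`.
#' @export
expected_manifest <- function(workload, config = tracker_config()) {
  rows <- list(data.frame(archived_name = basename(workload$script),
                          role = "code", copied = TRUE,
                          skip_reason = NA_character_,
                          stringsAsFactors = FALSE))
  pol_row <- function(name, size, role) {
    pol <- should_copy(name, size, role, config)
    data.frame(archived_name = name, role = role, copy = NA,
               copied = pol$copy, skip_reason = pol$skip_reason,
               stringsAsFactors = FALSE)[, c("archived_name", "role",
                                             "copied", "skip_reason")]
  }
  for (i in seq_len(nrow(workload$inputs)))
    rows[[length(rows) + 1L]] <- pol_row(workload$inputs$name[i],
                                         workload$inputs$size[i], "input")
  for (nm in workload$outputs)
    rows[[length(rows) + 1L]] <- pol_row(nm, 0, "output")
  # code files follow the output rule (always copied) unless excluded
  scr <- rows[[1L]]
  pol <- should_copy(basename(workload$script), 0, "code", config)
  scr$copied <- pol$copy
  scr$skip_reason <- pol$skip_reason
  rows[[1L]] <- scr
  out <- do.call(rbind, rows)
  out[order(out$archived_name), , drop = FALSE]
}
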
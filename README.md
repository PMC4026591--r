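# provtrack

Automatic provenance capture and checksummed archiving for R analyses.

Reported results of a statistical analysis are only worth anything if they
can be recapitulated from the study data — yet a single result is often a
function of dozens of data files that change over time, program files,
package versions, and (for bootstrap, permutation or simulation work) the
random seed that nobody wrote down. provtrack is for analysts who want
that record kept **automatically**: it runs an *unmodified* R script
inside a tracking session that records every file read and write, every
monitored random-number draw (plus the initial seed and generator), and
every external system call, each with a timestamp and a sketch of the
call stack. Ending the session freezes everything into a timestamped,
read-only archive with an MD5 manifest, and companion tools audit an
archive — or compare two — years later.

## What is recorded

Collection hooks are embedded at session start into the functions that
open files (`file`, `gzfile`, and the file-producing graphics devices),
generate random numbers (`runif`, `rnorm`, `sample` by default), and
issue system calls; they are removed without residue at session end. Each
event stores a three-element call-stack sketch `top_call / mid_call /
bot_call` — the outermost call, the immediate caller of the intercepted
primitive, and the primitive itself — so the record shows *which code*
touched *which file*, e.g. `run_tracked / write.table / file`.

The archive is a flat directory `[<base>-]YYYY-MM-DD-HH-MM-SS/` holding
one copy of every distinct file touched (role `code`, `input` or
`output`; inputs above a size cap or with excluded extensions are listed
but not copied), the serialized session details (`rc.details.rds`),
abbreviated detail tables as TSV, `MANIFEST.tsv` with per-file
size/MD5/mtime, and a plain-text `APPENDIX.txt` ready for pasting into a
Sweave/knitr report.

## Worked example

```r
library(provtrack)

wl <- make_worked_example("demo", n_points = 100)  # writes my.program.R
archive <- run_tracked(wl$script,
                       tracker_config(rng_init = list(seed = 123456789),
                                      archive_folder = "mydir"))
basename(archive)
#> [1] "mydir-2026-09-25-12-18-29"

d <- read_details(archive)
file_details(d)[, c("top_call", "mid_call", "bot_call", "description", "open")]
#>      top_call    mid_call bot_call            description open
#> 1 run_tracked      source     file /tmp/demo/my.program.R    r
#> 2 run_tracked write.table     file            pt.data.txt    w
#> 3 run_tracked  read.table     file            pt.data.txt   rt
#> 4 run_tracked        eval     jpeg        scatterplot.jpg    w

random_details(d)[, c("top_call", "mid_call", "bot_call", "seed", "kind")]
#>      top_call    mid_call       bot_call      seed             kind
#> 1 run_tracked run_tracked begin_tracking 123456789 Mersenne-Twister
#> 2 run_tracked        eval          rnorm        NA             <NA>
#> 3 run_tracked        eval          rnorm        NA             <NA>

check_archive(archive)
#> <archive audit> /tmp/demo/mydir-2026-09-25-12-18-29
#>   files checked: 7
#>   no discrepancies: archive matches its manifest
```

The four file-access rows are the script load, the tabular write, the
tabular read-back and the image write; the three random rows are the
automatic seed-initialization record (seed 123456789, the default) and
the two `rnorm` draws. The audit recomputes existence, size, MD5 and
modification time of every archived file against the manifest frozen at
build time — delete, truncate, byte-flip or touch any archived file and
`check_archive()` names it with the corresponding discrepancy.
`compare_archives(a, b)` diffs two archives; `create_zip_archive()` /
`check_zipfile()` do the same for a single-file zip form.

A shell entry point with subcommands `run`, `check`, `compare`,
`checkzip` and `appendix` is installed at `exec/provtrack`; audit
subcommands exit non-zero when discrepancies are found, so archives can
be verified from pipelines.

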
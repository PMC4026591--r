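---
title: "Automatic provenance capture for R analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic provenance capture for R analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provtrack)
```

## The problem

A statistical analysis of biomedical data is computationally a function of
many moving parts: input data files that are revised as samples accrue and
clinical follow-up is updated, program files, package versions, and — for
bootstrap, permutation and simulation procedures — the state of the random
number generator. A result is only reproducible if all of these are known.
Maintaining that record by hand is tedious and error-prone, and literate
programming tools (Sweave, knitr) document only the top-level code, not the
full set of files it touched or the seed it started from.

provtrack closes that gap at run time. A tracking session wraps an
*unmodified* analysis script and silently records three kinds of events,
each stamped with the time and a sketch of the call stack:

* **file accesses** — every file opened for reading or writing, with its
  open mode and full path;
* **random-number generation** — the initial seed and generator set at
  session start, and (optionally) every subsequent call to a monitored
  generator;
* **system calls** — commands handed to external software are noted
  verbatim, though what that software does internally is invisible to the
  session.

Ending the session materialises everything into a timestamped, read-only
archive: copies of the code, input and output files, an MD5 manifest, the
serialized session details, and a plain-text appendix that can be pasted
into a report. Companion tools later verify an archive against its
manifest, verify the zip variant, and compare two archives.

## The session model

`begin_tracking()` seeds the RNG (default seed 123456789 with the
interpreter's default generators), creates the in-memory detail store, and
embeds collection hooks into the monitored functions; `end_tracking()`
removes every hook, snapshots the environment (interpreter version, loaded
packages, platform attributes, command-line arguments, memory in use) and
builds the archive. `run_tracked(script)` wraps the two around
`source(script)` and records the script itself as a `code` entry. One
session per process: the single detail store makes nested sessions an
error, and a second run is simply a second session.

The interception contract is what matters: events are captured without any
modification of the user script, and the hooks are fully removable — after
`end_tracking()` the process's file and RNG behaviour is indistinguishable
from an untracked one. The mechanism used here is base R's
`trace()`/`untrace()` on the connection openers (`file`, `gzfile`), the
file-producing graphics devices (`jpeg`, `png`, `pdf`, and friends,
which do not open their file through a connection), the monitored RNG
functions, and `system`/`system2`. Hooks are resolved through the search
path, which patches both the attached package environment and the owning
namespace — this is why a `write.table()` call is caught at its internal
`file()` open. The hook body never touches the RNG and never opens a
file, so tracked workloads produce byte-identical outputs with tracking
on or off (asserted in the test suite).

### The call-stack sketch

Each record stores three function names: the outermost call (`top_call`),
the intercepted primitive (`bot_call`), and the immediate caller of that
primitive (`mid_call`); stacks shallower than three frames repeat what is
available, so a top-level `begin_tracking()` yields the same name three
times. Keeping the caller of the primitive (rather than, say, the second
frame) is what makes the sketch informative: a tabular write appears as
`... / write.table / file`, a device open as `... / eval / jpeg`. The full
invoking call and absolute path are kept alongside for the detailed view.

### Recording policies

All options live in `tracker_config()`; every one has a default so a
session can start with an empty configuration.

| option | default | why |
|---|---|---|
| `rng_init` | seed 123456789, default generators | replayability without user action |
| `details_file` | `rc.details.rds` | serialized details + manifest |
| `archive_folder` | none (timestamp-only name) | `base-YYYY-MM-DD-HH-MM-SS` otherwise |
| `maxsize_archive` | 1e9 bytes | copy inputs by default, but not GWAS-scale files |
| `do_not_archive` | empty | extensions (e.g. `CEL`) never copied |
| `skip_file_calls` | library/require/loadNamespace/requireNamespace | package loading touches many files; `sessionInfo()` already documents packages |
| `skip_empty_description` | `TRUE` | low-level `file("")` calls name no file |
| `rng_trace` | `TRUE` | set `FALSE` to speed up simulation-heavy code |
| `rng_functions` | `runif`, `rnorm`, `sample` | uniform, normal, integer sampling/permutation; `sample.int` excluded because `sample()` calls it internally and both hooks would double-count one draw |
| `print_trace` | `FALSE` | progress messages |

Open modes containing a write or append intent (`w`, `a`, `+`) are
write-like and mark the path as a session *output*; everything else is
read-like and marks an *input*. Read-write modes count as write-like: the
file's final state is a product of the run and must be preserved. Repeated
opens of the same path each produce a record — the log is per event — and
de-duplication happens only at archiving time.

## The archive

Each distinct path becomes one manifest entry: role `output` if any access
was write-like, else `input`; the tracked script is `code`. Files are
copied at session end, not at access time, so a file overwritten
mid-session is archived in its final state while the log still shows every
access; a file both written and read back is archived once. Copies
preserve content bytes and modification times; the copy policy
(`should_copy()`) skips inputs above `maxsize_archive` (reason
`too_large`) and any file with an excluded extension (reason
`extension_excluded`) — applied to inputs and outputs alike, since the
option's purpose is keeping bulky raw data out of the archive wherever it
appears. Outputs and code are otherwise always copied. A recorded file
that disappeared before archiving yields `copied = FALSE` with reason
`vanished` and a warning rather than an error.

The layout is a flat directory: copied files at top level, names
de-duplicated with deterministic `-2`, `-3`, … suffixes (the manifest maps
each archived name back to its original absolute path); `APPENDIX.txt`;
the two abbreviated detail tables as TSV; `MANIFEST.tsv`; and, written
last, `rc.details.rds` (a versioned, self-describing document holding
config, records, environment snapshot and the full manifest). Directory
names are timestamped and collision-suffixed, so consecutive builds never
overwrite. The directory is then locked read-only — advisory protection
against accidental edits; deliberate modification remains possible and is
precisely what the audit detects. The appendix is rendered purely from the
details document, so regenerating it from a reloaded archive reproduces
the stored text byte for byte.

`create_zip_archive()` packs the directory into one zip. The writer is
deliberately minimal: each member is deflate-compressed through a
`gzfile()` connection, and the CRC32 and compressed stream are lifted from
the resulting gzip container, so both come from zlib itself; reading and
auditing go through `utils::unzip`, an independent implementation, which
keeps the round trip honest.

## Auditing

`check_archive()` verifies every entry that was copied: existence, then
size, then MD5, then modification time, reporting the *first* failing
attribute per file — so truncation reads as a size mismatch, a same-size
byte flip as an MD5 mismatch, a `touch` as an mtime mismatch. An mtime
change with matching MD5 is reported at `metadata` severity, separately
counted, because the content-integrity claim still holds. Modification
times compare with a 2-second tolerance, the granularity of zip (DOS)
timestamps and of coarse filesystems. Files present in the directory but
absent from the manifest are reported as `extra_file` — an extension
beyond the recorded-manifest audit, flagged as such in the documentation.
`compare_archives()` keys on the archive-internal name (archives move
between machines), reports every differing attribute of name-matched
files, and lists unmatched names per side; `check_zipfile()` audits zip
members against the embedded manifest, reading exact member times from the
zip central directory. Audit subcommands of the CLI exit 0 only on a
clean report, for scripted verification.

## Fixture workloads

`make_worked_example()` emits a small script covering each monitored
pathway once — two normal samples, a tabular write, a tabular read-back,
and a scatterplot through a file-producing graphics device — with a
footprint known in advance: exactly 4 file-access records (script read,
tabular write, tabular read, image write) and 3 random-event records
(initialization plus two draws), independent of the sample size.
`make_stress_workload()` generalises this: configurable counts and sizes
of inputs, outputs, RNG draws and system calls, with input bytes drawn
reproducibly from a seed, and `expected_manifest()` computes the archive
manifest any configuration must produce by pure arithmetic — the tracker
is therefore tested against predictions made without the tracker.

What the generators emulate is the *I/O shape* of an analysis, not its
content: files are opaque byte streams to the tracker, so pixel content,
statistical validity and file-format details are irrelevant and
deliberately not modelled. Passing tests show that events of each kind are
captured completely and policies applied exactly; they do not show
behaviour under workloads the hooks cannot see (see limitations).

## Numerical and design choices

* Paths are made absolute *before* normalization: a file first written and
  later read must de-duplicate to one key even though it did not exist at
  the first event.
* Event times carry a monotonic sequence counter; ties in wall-clock time
  cannot reorder records.
* The worked example defaults to 100 points and the JPEG device (falling
  back to PNG where the build lacks JPEG support); the test suite uses
  workloads of ≤ 7 files and inputs of ≤ 2 MB, which exercise every policy
  branch while keeping the whole suite under ten seconds.
* `maxsize_archive` defaults to 1 GB: permissive enough that by default
  everything but truly bulky inputs is frozen.
* Read-only locking uses permission bits (444 files / 555 directory);
  for privileged users POSIX permissions are advisory, which is consistent
  with treating the lock as protection against *inadvertent* change only.

## Limitations

* File accesses made by external processes launched via `system()` are not
  captured; only the command line is noted.
* An RNG call made *from inside another package's compiled or namespaced
  code* can bypass a hook if that namespace resolves the generator through
  its own imports rather than the search path; draws made from user code
  (scripts, functions defined in the workspace) are always seen.
* RNG streams are monitored, never controlled: beyond the initial seeding
  the session does not alter generation, so properly implemented serial or
  parallel RNG is unaffected.
* One session per process; combining details from parallel sessions is out
  of scope.
* The archive is not a self-contained execution environment: recapitulating
  a run still requires R and the recorded packages, with file paths
  adjusted to the archived copies (the manifest records both names for
  that purpose).
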
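Package: provtrack
Title: Automatic Provenance Capture and Checksummed Archiving for R Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Runs an unmodified R analysis script inside a tracking session
    that silently records every file read and write, every random-number
    generation event (including the initial seed and generator), and every
    external system call, together with a sketch of the call stack at each
    event. At session end it materialises a timestamped, read-only archive
    holding copies of the code, input and output files, an MD5 manifest, a
    serialized details record and a plain-text appendix suitable for
    inclusion in literate-programming reports. Companion tools audit an
    archive against its recorded manifest, audit a zip variant, and compare
    two archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    utils,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
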
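Package: axiszone
Title: Zone-Specific Transcript Identification from Anterior-Posterior RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns transcripts to anterior-posterior body zones from
    multi-zone bulk RNA-seq count matrices. Implements counts-per-million
    (CPM) low-expression filtering, trimmed-mean-of-M-values (TMM)
    normalization with effective library sizes, one-vs-rest
    negative-binomial conditional exact tests, and composite
    zone-membership codes (e.g. "2.1") that name the zones a transcript is
    specific to, ordered by expression. Includes a negative-binomial
    simulator of zoned count matrices with planted axial expression
    archetypes so the whole pipeline can be validated against known truth,
    plus quantile-normalization and distribution diagnostics for choosing
    the expression filter cutoff.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    limma,
    yaml,
    jsonlite
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
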
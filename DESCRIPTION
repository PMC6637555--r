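Package: sdpsearch
Title: Spectrum Dot Product Peptide Database Search with Dynamic Task Scheduling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale shotgun-proteomics database search engine built
    around the boolean spectrum dot product (SDP) score. Proteins are
    digested in silico (Trypsin, AspN or LysC with missed cleavages and
    fixed modifications), candidate peptides are retrieved from a
    mass-sorted index by binary search over a precursor tolerance window,
    and each MS/MS spectrum is scored against its candidates either with a
    two-pass reference algorithm or with a fused single-pass variant that
    streams candidates through a bounded top-k buffer. A dynamic feedback
    task scheduler assigns spectrum chunks to heterogeneous workers in
    proportion to measured performance factors (CPU utilization, task-queue
    length, memory usage) and rebalances unstarted work until the load
    imbalance falls below a threshold. The end-to-end pipeline moves chunks
    through bounded circular request/response queues (double buffering) and
    merges per-chunk results deterministically, so serial and parallel runs
    produce identical reports. A fixtures module generates synthetic
    proteomes and spectra with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Collate:
    'masses.R'
    'digestion.R'
    'config.R'
    'formats_io.R'
    'theoretical.R'
    'scoring.R'
    'scheduler.R'
    'pipeline.R'
    'fixtures.R'
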
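Package: crisprofile
Title: Mutation Profiling and Simulation for CRISPR Diversifying Base Editors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the activity of guide-directed cytidine deaminase base
    editors from amplicon sequencing: paired-read merging, glocal alignment,
    per-position pileup statistics, background-subtracted substitution and
    indel rates, PAM-anchored multi-guide combination, substitution-spectrum
    matrices, mutagenic-window extent estimation, per-generation mutation
    rates from culture passage records, and saturation-binding affinity fits
    for titration data. Includes a forward simulator of targeted deaminase
    mutagenesis (WRCY/AGCT motif preference, positional window, C:G bias,
    generation-compounded rates) that generates reference, reads and
    ground-truth mutation tables so the whole pipeline is testable without
    external data. All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
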
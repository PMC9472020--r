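Package: ntpquant
Title: Quantitative Pipelines for Non-Thermal Plasma Tumor Therapy Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable computational pipelines for preclinical non-thermal plasma
    (NTP) therapy studies of melanoma: DAPI-anchored nuclei segmentation and
    per-cell immunofluorescence quantification, dual-marker double-positive cell
    counting (e.g. CD3+/FOXP3+ regulatory T cells), discharge pulse-energy
    dosimetry with displacement-current correction, and a combined
    significance-score ranking feeding preranked gene-set enrichment with
    permutation-based normalized enrichment scores and false discovery rates.
    Includes synthetic ground-truth generators for microscopy images,
    oscilloscope waveforms and differential-expression tables so every stage is
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    knitr
Config/testthat/edition: 3
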
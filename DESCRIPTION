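Package: netstim
Title: Network-Specific TMS Effects on Brain Metabolism and Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying network-specific effects of repetitive
    transcranial magnetic stimulation (TMS) with combined FDG-PET and resting-state
    fMRI. Implements functional-connectivity-guided derivation of anti-correlated
    dorsolateral prefrontal stimulation targets from a subgenual cingulate seed map,
    BOLD denoising (nuisance regression with temporal derivatives, zero-phase
    low-pass filtering), Fisher z seed-based connectivity maps and region-pair
    matrices, whole-brain-normalized standardized uptake value (SUV) deltas with
    target exclusion, paired group inference with Cohen's d, sign-flipping
    permutation max-T family-wise correction, and across-subject coupling between
    metabolic and connectivity changes. Includes a synthetic multi-network
    BOLD/PET cohort generator with a ground-truth ledger so every stage is
    testable without real data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
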
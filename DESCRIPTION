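Package: hftmspc
Title: Hierarchical Frequency Tagging EEG Analysis with Multispectral Phase
    Coherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hierarchical frequency-tagging (HFT) EEG experiments that
    combine semantic wavelet-induced frequency tagging (SWIFT) of object
    recognition with steady-state visual evoked potential (SSVEP) contrast
    modulation. Implements SWIFT stimulus synthesis by cyclic wavelet-coefficient
    scrambling, trial schedule construction, a synthetic-EEG generator with
    stimulus-locked and latency-jittered nonlinear interactions, amplitude and
    artifact based preprocessing and exclusion rules, exact-bin Fourier
    decomposition with neighbour-based amplitude signal-to-noise ratios,
    enumeration of intermodulation components, the multispectral phase coherence
    (MSPC) statistic in stimulus-referenced and response-referenced variants
    alongside the phase-locking value, and mixed-model likelihood-ratio contrasts
    over a posterior electrode region of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    signal,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
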
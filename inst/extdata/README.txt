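Worked-example inputs for the evaluation operations:

- example_n_confusion.csv / example_m_confusion.csv: N- and M-stage
  confusion matrices from a published clinical evaluation of automated
  PROMISE miTNM staging (rows = annotation-derived stage, columns =
  predicted stage, 52 subjects).
- example_detection_counts.csv: pooled true-positive / false-positive /
  false-negative finding counts from the same evaluation.

These files are inputs for stageAgreement() and detectionRates() worked
examples; see the package vignette.
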
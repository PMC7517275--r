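Reference fixtures for the LDA tissue-classification tables.

gradient_lda_confusion.csv / pca_lda_confusion.csv
  Published LDA confusion matrices (rows = true class, columns = predicted
  class, fixed order fat/skin/nerve/bone/muscle) from the ex vivo porcine
  diffuse-reflectance study this package models: the characteristics
  (gradient-feature) path and the 40-component PCA path. Row sums are the
  per-class test supports (280, 232, 280, 304, 216 in both).

*_reference_metrics.csv
  The corresponding published per-class specificity (precision convention)
  and sensitivity values, their support-weighted averages, and the LDA
  accuracy, as printed (2 decimals per class, 3 decimals accuracy).
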
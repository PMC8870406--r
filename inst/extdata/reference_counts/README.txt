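Reference confusion counts from a label-free colorectal screening
experiment (132-patient tissue microarray; 32 held-out test cores with 116
cancer and 251 normal ground-truth glands). Used as regression fixtures for
report generation:

  detection_confusion.csv  gland detection over the test cores; rows are
                           actual classes, columns predicted; "stroma" is
                           the unmatched/background pseudo-class (missed
                           glands in its column, false detections in its
                           row).
  core_confusion.csv       core-level diagnosis over the 32 test cores.
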
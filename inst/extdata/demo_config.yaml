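# Demo configuration for conformalqc::run_pipeline().
#
# Simulates a prostate-biopsy-style grading cohort (benign + five ISUP grade
# groups), splits it 90/10 into proper-training and calibration parts grouped
# by subject, builds a Mondrian calibrator, and evaluates a baseline test set
# plus two shift scenarios (a score distortion standing in for an external
# scanner, and a contamination scenario standing in for atypical tissue).

labels: [benign, ISUP1, ISUP2, ISUP3, ISUP4, ISUP5]
ordinal: true

# class mix of a screening-trial training cohort; raw counts are normalized
prevalence: [3724, 1530, 539, 263, 469, 426]

n_train: 3000
n_test: 400
mode: class_conditional
discriminability: 8        # Dirichlet concentration added to the true class
biopsies_per_subject: 6.5  # subjects contribute several biopsies each
calibration_fraction: 0.10

confidences:
  global67: 0.67
  global80: 0.80
  classwise:               # higher confidence where the classifier is strong
    benign: 0.85
    ISUP1: 0.85
    ISUP2: 0.67
    ISUP3: 0.67
    ISUP4: 0.67
    ISUP5: 0.67

scenarios:
  external_scanner:
    kind: temperature
    magnitude: 2.0         # T > 1 flattens every probability vector
  atypical_tissue:
    kind: contamination
    magnitude: 0.6         # fraction of rows replaced by near-uniform scores

drift_mode: labeled
drift_alpha: 0.05
power_grid: [10, 25, 50, 100, 200]
power_reps: 50
power_threshold: 0.8

smoothed: false
master_seed: 20221215
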
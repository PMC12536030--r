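# Example run configuration for the retfuse pipeline.
# Every stage is reproducible from this file plus the seed.
seed: 1
scenario:
  n_cases: 200
  # class_weights default to uniform over the five retinal classes
  submodels:
    - {id: text-1, target_accuracy: 0.45, sharpness: 6}
    - {id: text-2, target_accuracy: 0.60, sharpness: 8}
    - {id: text-3, target_accuracy: 0.35, sharpness: 4}
    - {id: text-4, target_accuracy: 0.30, sharpness: 3}
    - {id: text-5, target_accuracy: 0.30, sharpness: 5}
    - {id: text-6, target_accuracy: 0.40, sharpness: 6}
    - {id: image-1, target_accuracy: 0.55, sharpness: 7,
       modality: image, coverage: 0.3}
split:
  calibration_size: 20
  test_fraction: 0.3
confidence:
  epsilon: 1.0e-9
  length_divisor: 10.0
  length_unit: characters
evaluation:
  k_values: [1, 3]
  ece_bins: 10
triage:
  screening_min: 0.15
  monitoring_min: 0.35
  referral_min: 0.60
  referral_classes: [SevereDR, Glaucoma, AMD]
methods: [rank, reliability_entropy]
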
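{
  "phase_duration_mean_s": {
    "pre_reference": 1.9,
    "reference": 1.32,
    "post_reference": 0.78,
    "action": 1.68,
    "post_action": 0.81
  },
  "phase_duration_cv": 0.4,
  "instructor_dist": {
    "pre_reference": {
      "Reference": 0.32,
      "Other": 0.16,
      "Target": 0.24,
      "Person": 0.02,
      "Unmapped": 0.26
    },
    "reference": {
      "Reference": 0.45,
      "Other": 0.22,
      "Target": 0.16,
      "Person": 0.05,
      "Unmapped": 0.12
    },
    "post_reference": {
      "Reference": 0.36,
      "Other": 0.27,
      "Target": 0.22,
      "Person": 0.05,
      "Unmapped": 0.1
    },
    "action": {
      "Reference": 0.12,
      "Other": 0.24,
      "Target": 0.5,
      "Person": 0.02,
      "Unmapped": 0.12
    },
    "post_action": {
      "Reference": 0.05,
      "Other": 0.48,
      "Target": 0.2,
      "Person": 0.05,
      "Unmapped": 0.22
    }
  },
  "worker_dist": {
    "pre_reference": {
      "Reference": 0.0,
      "Other": 0.66,
      "Target": 0.14,
      "Person": 0.12,
      "Unmapped": 0.08
    },
    "reference": {
      "Reference": 0.02,
      "Other": 0.48,
      "Target": 0.16,
      "Person": 0.2,
      "Unmapped": 0.14
    },
    "post_reference": {
      "Reference": 0.4,
      "Other": 0.14,
      "Target": 0.16,
      "Person": 0.1,
      "Unmapped": 0.2
    },
    "action": {
      "Reference": 0.42,
      "Other": 0.14,
      "Target": 0.06,
      "Person": 0.26,
      "Unmapped": 0.12
    },
    "post_action": {
      "Reference": 0.14,
      "Other": 0.08,
      "Target": 0.46,
      "Person": 0.2,
      "Unmapped": 0.12
    }
  },
  "rho": {
    "pre_reference": 0.332,
    "reference": 0.4479,
    "post_reference": 0.4339,
    "action": 0.3591,
    "post_action": 0.36
  },
  "lead_ms": {
    "pre_reference": 0,
    "reference": 700,
    "post_reference": -300,
    "action": -50,
    "post_action": 300
  },
  "dwell_mean_ms": {
    "instructor": 280,
    "worker": 240
  },
  "dwell_cv": {
    "instructor": 0.5,
    "worker": 0.5
  },
  "instructor_lead_mean_ms": null,
  "instructor_lead_cv": null,
  "worker_latency_mean_ms": 1690,
  "worker_latency_cv": 0.6,
  "repair_prob": 0.25,
  "repair_worker_delta": {
    "pre_reference": {
      "Reference": 0,
      "Other": -0.12,
      "Target": 0.12,
      "Person": 0,
      "Unmapped": 0
    },
    "reference": {
      "Reference": 0,
      "Other": 0.18,
      "Target": -0.08,
      "Person": -0.1,
      "Unmapped": 0
    },
    "post_reference": {
      "Reference": -0.22,
      "Other": 0.22,
      "Target": 0,
      "Person": 0,
      "Unmapped": 0
    },
    "action": {
      "Reference": 0,
      "Other": 0,
      "Target": 0,
      "Person": 0,
      "Unmapped": 0
    },
    "post_action": {
      "Reference": 0,
      "Other": 0,
      "Target": 0,
      "Person": 0,
      "Unmapped": 0
    }
  },
  "repair_rho_factor": {
    "pre_reference": 1,
    "reference": 1.0,
    "post_reference": 0.6,
    "action": 1,
    "post_action": 1
  },
  "n_ingredients": 23,
  "inter_sequence_gap_ms": 1000,
  "seed": null
}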
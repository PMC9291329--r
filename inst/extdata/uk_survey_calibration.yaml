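# Default calibration: hospital-level aggregates of the UK NHS staff survey
# (n = 413 hospitals). Eight organizational factor scores on a 0-10 scale and
# the proportion of staff reporting patient-safety errors on [0, 1].
# Marginals are summary moments; correlations are Spearman rank coefficients
# (inter-factor block plus factor-target column).
sample_size: 413
target: patient_safety_errors
marginals:
  - name: equality_diversity_inclusion
    mean: 9.05
    sd: 0.26
    low: 8.07
    high: 9.56
    scale_max: 10
  - name: safety_culture
    mean: 6.60
    sd: 0.25
    low: 5.68
    high: 7.23
    scale_max: 10
  - name: health_wellbeing
    mean: 5.95
    sd: 0.29
    low: 5.19
    high: 6.78
    scale_max: 10
  - name: immediate_managers
    mean: 6.71
    sd: 0.23
    low: 6.00
    high: 7.41
    scale_max: 10
  - name: quality_of_care
    mean: 7.46
    sd: 0.21
    low: 6.67
    high: 8.20
    scale_max: 10
  - name: team_working
    mean: 6.53
    sd: 0.20
    low: 5.87
    high: 7.17
    scale_max: 10
  - name: safe_environment_bh
    mean: 7.91
    sd: 0.27
    low: 6.99
    high: 8.49
    scale_max: 10
  - name: safe_environment_violence
    mean: 9.40
    sd: 0.09
    low: 9.13
    high: 9.67
    scale_max: 10
  - name: patient_safety_errors
    mean: 0.29
    sd: 0.03
    low: 0.19
    high: 0.39
    scale_max: 1
# Lower triangle of the 8x8 inter-factor Spearman matrix, row by row in the
# order the factors are listed above.
factor_correlations:
  - pair: [safety_culture, equality_diversity_inclusion]
    rho: 0.14
  - pair: [health_wellbeing, equality_diversity_inclusion]
    rho: 0.51
  - pair: [health_wellbeing, safety_culture]
    rho: 0.54
  - pair: [immediate_managers, equality_diversity_inclusion]
    rho: 0.27
  - pair: [immediate_managers, safety_culture]
    rho: 0.78
  - pair: [immediate_managers, health_wellbeing]
    rho: 0.60
  - pair: [quality_of_care, equality_diversity_inclusion]
    rho: -0.10
  - pair: [quality_of_care, safety_culture]
    rho: 0.57
  - pair: [quality_of_care, health_wellbeing]
    rho: 0.42
  - pair: [quality_of_care, immediate_managers]
    rho: 0.42
  - pair: [team_working, equality_diversity_inclusion]
    rho: 0.25
  - pair: [team_working, safety_culture]
    rho: 0.73
  - pair: [team_working, health_wellbeing]
    rho: 0.61
  - pair: [team_working, immediate_managers]
    rho: 0.82
  - pair: [team_working, quality_of_care]
    rho: 0.52
  - pair: [safe_environment_bh, equality_diversity_inclusion]
    rho: 0.67
  - pair: [safe_environment_bh, safety_culture]
    rho: 0.47
  - pair: [safe_environment_bh, health_wellbeing]
    rho: 0.70
  - pair: [safe_environment_bh, immediate_managers]
    rho: 0.53
  - pair: [safe_environment_bh, quality_of_care]
    rho: 0.17
  - pair: [safe_environment_bh, team_working]
    rho: 0.47
  - pair: [safe_environment_violence, equality_diversity_inclusion]
    rho: 0.01
  - pair: [safe_environment_violence, safety_culture]
    rho: 0.20
  - pair: [safe_environment_violence, health_wellbeing]
    rho: 0.04
  - pair: [safe_environment_violence, immediate_managers]
    rho: 0.10
  - pair: [safe_environment_violence, quality_of_care]
    rho: -0.01
  - pair: [safe_environment_violence, team_working]
    rho: 0.10
  - pair: [safe_environment_violence, safe_environment_bh]
    rho: 0.11
# Spearman correlation of each factor with the patient-safety-error target.
target_correlations:
  equality_diversity_inclusion: -0.36
  safety_culture: -0.22
  health_wellbeing: -0.58
  immediate_managers: -0.17
  quality_of_care: -0.35
  team_working: -0.21
  safe_environment_bh: -0.49
  safe_environment_violence: -0.10
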
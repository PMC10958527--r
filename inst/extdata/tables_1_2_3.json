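{
  "meta": {
    "description": "Published model inputs: baseline weekly transition probabilities (cumulative scale with 95% CIs), treatment-effect risk ratios, and CAMP product costs.",
    "currency": "USD",
    "cycle_length_weeks": 1
  },
  "baseline_transitions": {
    "columns": ["parameter", "mean", "ci_lower", "ci_upper", "period_weeks", "weekly_printed", "source"],
    "rows": [
      {"parameter": "p_heal_post_infection", "mean": 0.3300, "ci_lower": 0.2839, "ci_upper": 0.3761, "period_weeks": 12, "weekly_printed": 0.0275, "source": "meta-analysis (Healing)"},
      {"parameter": "p_amputate_from_infection", "mean": 0.1740, "ci_lower": 0.1310, "ci_upper": 0.2170, "period_weeks": 52, "weekly_printed": 0.0033, "source": "Ndosi (Amputation)"},
      {"parameter": "p_heal_soc", "mean": 0.3829, "ci_lower": 0.3189, "ci_upper": 0.4468, "period_weeks": 12, "weekly_printed": 0.0319, "source": "Su (DFU to healing SC)"},
      {"parameter": "p_infect", "mean": 0.1961, "ci_lower": 0.1416, "ci_upper": 0.2506, "period_weeks": 12, "weekly_printed": 0.0163, "source": "Su (DFU to infection)"},
      {"parameter": "p_amputate_from_dfu", "mean": 0.0681, "ci_lower": 0.0534, "ci_upper": 0.0828, "period_weeks": 12, "weekly_printed": 0.0057, "source": "Armstrong (DFU to amputation)"},
      {"parameter": "p_die_dfu", "mean": 0.0610, "ci_lower": 0.0141, "ci_upper": 0.1079, "period_weeks": 52, "weekly_printed": 0.0012, "source": "Armstrong (DFU no infection mortality)"},
      {"parameter": "p_die_post_amputation", "mean": 0.1028, "ci_lower": 0.0433, "ci_upper": 0.1623, "period_weeks": 52, "weekly_printed": 0.0020, "source": "Armstrong (DFU mortality amputation)"},
      {"parameter": "p_die_infection", "mean": 0.1505, "ci_lower": 0.1100, "ci_upper": 0.1910, "period_weeks": 52, "weekly_printed": 0.0029, "source": "Ndosi (Mortality following infection)"},
      {"parameter": "p_die_background", "mean": 0.0487, "ci_lower": null, "ci_upper": null, "period_weeks": 52, "weekly_printed": 0.0009, "source": "US Life Tables (all ages)"}
    ],
    "notes": [
      "CIs and means are on the cumulative (source-period) scale; weekly_printed is the published weekly value obtained by linear division by period_weeks.",
      "Trial-derived rows carry a 12-week source period; annual rows carry 52 weeks. Periods were inferred by reproducing each printed weekly value.",
      "The 'Healing 33.00%' meta-analysis row is mapped to healing from the infected pathway and 'DFU to healing SC 38.29%' to standard-of-care healing of the uncomplicated ulcer; both mappings are configuration-exposed."
    ]
  },
  "age_band_mortality": {
    "columns": ["age_band", "annual", "weekly_printed"],
    "rows": [
      {"age_band": "<55", "annual": 0.0022, "weekly_printed": 0.0000},
      {"age_band": "55-64", "annual": 0.0089, "weekly_printed": 0.0002},
      {"age_band": "65-74", "annual": 0.0186, "weekly_printed": 0.0004},
      {"age_band": ">=75", "annual": 0.1385, "weekly_printed": 0.0027}
    ]
  },
  "treatment_effects": {
    "columns": ["strategy", "rr_healing", "ci_lower", "ci_upper"],
    "rows": [
      {"strategy": "vCPM", "rr_healing": 2.91, "ci_lower": 1.61, "ci_upper": 5.26},
      {"strategy": "dHACM", "rr_healing": 1.63, "ci_lower": 1.32, "ci_upper": 2.02},
      {"strategy": "hFDS", "rr_healing": 1.31, "ci_lower": 1.01, "ci_upper": 1.69},
      {"strategy": "BLCC", "rr_healing": 1.55, "ci_lower": 1.23, "ci_upper": 1.94},
      {"strategy": "HSAM", "rr_healing": 1.64, "ci_lower": 1.01, "ci_upper": 2.68},
      {"strategy": "HAMA", "rr_healing": 2.62, "ci_lower": 1.64, "ci_upper": 4.16}
    ],
    "class_effects": {
      "rr_infection": {"mean": 0.49, "ci_lower": 0.28, "ci_upper": 0.85},
      "rr_amputation": {"mean": 0.27, "ci_lower": 0.17, "ci_upper": 0.44}
    },
    "notes": [
      "rr_healing is the wound-closure risk ratio versus standard of care, product-specific.",
      "Infection and amputation risk ratios are class effects shared by every CAMP."
    ]
  },
  "product_costs": {
    "columns": ["strategy", "cost_per_cm2", "wound_area_cm2", "cost_per_application", "n_applications_base", "per_treatment_printed", "n_applications_trial"],
    "rows": [
      {"strategy": "BLCC", "cost_per_cm2": 30, "wound_area_cm2": 44, "cost_per_application": 1338.92, "n_applications_base": 4, "per_treatment_printed": 5355.68, "n_applications_trial": 5},
      {"strategy": "hFDS", "cost_per_cm2": 32, "wound_area_cm2": 37.5, "cost_per_application": 1201.125, "n_applications_base": 4, "per_treatment_printed": 4804.50, "n_applications_trial": 7.1},
      {"strategy": "vCPM", "cost_per_cm2": 134, "wound_area_cm2": 6, "cost_per_application": 802.44, "n_applications_base": 4, "per_treatment_printed": 3209.76, "n_applications_trial": 6},
      {"strategy": "HAMA", "cost_per_cm2": 124, "wound_area_cm2": 6, "cost_per_application": 746.52, "n_applications_base": 4, "per_treatment_printed": 2986.08, "n_applications_trial": 4},
      {"strategy": "HSAM", "cost_per_cm2": 584, "wound_area_cm2": 5, "cost_per_application": 2918.35, "n_applications_base": 4, "per_treatment_printed": 11673.40, "n_applications_trial": 4},
      {"strategy": "dHACM", "cost_per_cm2": 155, "wound_area_cm2": 6, "cost_per_application": 933.00, "n_applications_base": 4, "per_treatment_printed": 3264.45, "n_applications_trial": 3.5}
    ],
    "notes": [
      "cost_per_application is cost_per_cm2 x wound_area_cm2 (the published per-application figures are rounded to whole dollars).",
      "The dHACM row is internally inconsistent in the source ($933 x 4 = $3,732, not the printed $3,264.45); the printed per-treatment total is stored as authoritative and per_treatment_printed takes precedence over recomputation for that strategy.",
      "n_applications_trial holds the trial-reported application counts used in the applications sensitivity scenario (HAMA and HSAM keep the base-case 4)."
    ]
  }
}
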
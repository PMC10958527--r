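{
  "meta": {
    "description": "Published per-patient results used as stage inputs when testing the ranking and sensitivity stages in isolation from the cohort engine (state costs and utilities behind the published cost/QALY columns are not printed, so the engine cannot reproduce them exactly)."
  },
  "base_case": {
    "columns": ["strategy", "cost", "qalys", "healed_wounds"],
    "rows": [
      {"strategy": "vCPM", "cost": 10907, "qalys": 0.783, "healed_wounds": 0.914},
      {"strategy": "HAMA", "cost": 11470, "qalys": 0.780, "healed_wounds": 0.903},
      {"strategy": "dHACM", "cost": 15862, "qalys": 0.764, "healed_wounds": 0.828},
      {"strategy": "hFDS", "cost": 18430, "qalys": 0.763, "healed_wounds": 0.816},
      {"strategy": "BLCC", "cost": 19498, "qalys": 0.757, "healed_wounds": 0.775},
      {"strategy": "SoC", "cost": 19862, "qalys": 0.732, "healed_wounds": 0.601},
      {"strategy": "HSAM", "cost": 24214, "qalys": 0.763, "healed_wounds": 0.829}
    ]
  },
  "anchored_published": {
    "columns": ["strategy", "inc_cost", "inc_healed_wounds", "inc_qalys", "cost_per_healed", "cost_per_qaly"],
    "rows": [
      {"strategy": "vCPM", "inc_cost": -8956, "inc_healed_wounds": 0.313, "inc_qalys": 0.051, "cost_per_healed": null, "cost_per_qaly": null},
      {"strategy": "HAMA", "inc_cost": -8393, "inc_healed_wounds": 0.302, "inc_qalys": 0.048, "cost_per_healed": null, "cost_per_qaly": null},
      {"strategy": "dHACM", "inc_cost": -4000, "inc_healed_wounds": 0.227, "inc_qalys": 0.033, "cost_per_healed": null, "cost_per_qaly": null},
      {"strategy": "hFDS", "inc_cost": -364, "inc_healed_wounds": 0.174, "inc_qalys": 0.025, "cost_per_healed": null, "cost_per_qaly": null},
      {"strategy": "BLCC", "inc_cost": -1432, "inc_healed_wounds": 0.216, "inc_qalys": 0.031, "cost_per_healed": null, "cost_per_qaly": null},
      {"strategy": "HSAM", "inc_cost": 4352, "inc_healed_wounds": 0.228, "inc_qalys": 0.031, "cost_per_healed": 19077, "cost_per_qaly": 139480}
    ]
  },
  "applications_scenario": {
    "columns": ["strategy", "cost", "healed_wounds"],
    "rows": [
      {"strategy": "HAMA", "cost": 11470, "healed_wounds": 0.903},
      {"strategy": "vCPM", "cost": 12511, "healed_wounds": 0.9135},
      {"strategy": "dHACM", "cost": 15862, "healed_wounds": 0.828},
      {"strategy": "BLCC", "cost": 19769, "healed_wounds": 0.816},
      {"strategy": "SoC", "cost": 19862, "healed_wounds": 0.601},
      {"strategy": "hFDS", "cost": 23222, "healed_wounds": 0.775},
      {"strategy": "HSAM", "cost": 24214, "healed_wounds": 0.829}
    ],
    "published_frontier_icer_per_healed": 99657,
    "notes": [
      "vCPM's healed-wound effect is reconstructed as HAMA 0.903 plus the scenario table's own printed incremental effect 0.0105 (the 3-dp rounded per-strategy values 0.914/0.903 would give increment 0.011); the published frontier ICER $99,657 corresponds to the unrounded increment."
    ]
  }
}
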
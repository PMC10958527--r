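# Base-case pipeline configuration: seven strategies, 52-week horizon,
# published conventions. Stochastic stages (psa, synth) require a seed.
strategies: [SoC, vCPM, HAMA, dHACM, hFDS, BLCC, HSAM]
horizon_weeks: 52
effect_measure: healed_wounds
conversion: linear
infection_healing_to: unhealed
add_background_mortality: false
applications: base
stages: [run]
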
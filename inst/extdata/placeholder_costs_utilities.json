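{
  "meta": {
    "assumption_level": true,
    "description": "SYNTHETIC placeholder health-state weekly costs and utilities. The source analysis cites these inputs from literature (state costs: Rice 2014, Hicks 2016, Franklin 2014; utilities: Redekop 2004 time-trade-off) without printing the values. The numbers below were chosen once at the scale of that literature and are free configuration inputs; cost and QALY outputs that depend on them are assumption-level, not reproductions.",
    "currency": "USD"
  },
  "state_costs_weekly": {
    "unhealed": 600,
    "healed": 0,
    "infected": 900,
    "post_amputation": 150
  },
  "event_costs": {
    "amputation": 35000
  },
  "utilities_annual": {
    "unhealed": 0.75,
    "healed": 0.84,
    "infected": 0.71,
    "post_amputation": 0.63,
    "dead": 0
  },
  "notes": [
    "Post states inherit their parent state's weekly cost and utility.",
    "The healed-state cost is zero by the source analysis's own assumption.",
    "The amputation event cost is a one-off charged on entry (hospitalization plus one year of subsequent care); the post-amputation weekly rate covers ongoing ambulatory care."
  ]
}
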
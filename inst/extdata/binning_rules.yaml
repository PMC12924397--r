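version: 1
dialects:
  FMCH:
    description: >
      Single-label dialect: each video carries one mutually exclusive
      behaviour code and one mutually exclusive locomotion code.
    behaviour_vocabulary: [eating, ruminating, travelling, stationary awake,
                           napping, other]
    locomotion_vocabulary: [napping, stationary awake, running,
                            wading/swimming, walking]
    two_state:
      field: locomotion
      map:
        napping: stationary
        stationary awake: stationary
        running: travelling
        wading/swimming: travelling
        walking: travelling
    three_state:
      field: behaviour
      map:
        ruminating: stationary
        stationary awake: stationary
        napping: stationary
        eating: foraging
        travelling: travelling
    exclusion: any record whose behaviour code is "other" is EXCLUDED.
  RFCH:
    description: >
      Multi-label dialect: each video carries a non-empty set of labels;
      deterministic precedence rules reduce the set to one category.
    vocabulary: [eating, foraging, drinking, laying, walking, ruminating,
                 vigilant, running, swimming, other]
    aliases:
      vigilance: vigilant
    two_state:
      rule_order:
        - {labels: [walking, running, swimming], category: travelling}
        - {labels: [eating, drinking, laying, ruminating, vigilant, foraging],
           category: stationary}
    three_state:
      rule_order:
        - {labels: [laying, vigilant, ruminating], category: stationary}
        - {labels: [walking, running, swimming], category: travelling}
        - {labels: [eating, drinking, foraging], category: foraging}
      note: later rules override earlier ones.
    exclusion: any record containing "other" is EXCLUDED.
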
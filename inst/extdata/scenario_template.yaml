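# Scenario configuration template.
# Strategies: the no-screening reference arm is always run implicitly.
strategies:
  - kind: colonoscopy_q10y            # screening colonoscopy, offered once per 10-year horizon
  - kind: biennial_fit                # conventional FIT every 2 years, preset cut-off 17 ug/g
    cutoff: 17
  - kind: gateopener                  # single low-threshold FIT per 10 years; positives
    cutoff: 8                         #   proceed to colonoscopy. Supported cut-offs:
  - kind: gateopener                  #   17, 10, 8, 6, 4, 3 ug Hb/g feces.
    cutoff: 3
ages: [50, 60, 70]                    # starting ages of the previously unscreened cohorts
sexes: [female, male]                 # simulated separately; pooled summaries derived afterwards
cohort_size: 100000
horizon_years: 10
mode: expectation                     # expectation | microsim
seed: 1
# adherence: either a preset name (base | adherence60 | dropout30) or a block:
adherence:
  p_colonoscopy: 0.15                 # uptake of the 10-yearly colonoscopy offer
  p_fit_first: 0.50                   # first-offer FIT participation
  dropout: 0.40                       # cumulative drop-out over the biennial rounds
  p_diag_colonoscopy: 0.80            # compliance with colonoscopy after a positive FIT
colonoscopy:
  miss_nonadvanced: 0.26              # per-lesion miss probabilities at colonoscopy
  miss_advanced: 0.09
  miss_preclinical_crc: 0.05
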
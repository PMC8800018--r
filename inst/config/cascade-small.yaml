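# Small test profile: the full-scale cascade scaled by 1/10, suitable for a
# ~20,000-compound synthetic screen.
dock_keep: 1000
bayes_keep: 200
druglike_keep: 20
diversity_keep: 10
final_keep: 5
rank_rule: best_across_conformations
nbc_bins: 10
similarity_cutoff: 0.8
similarity_strict: false
hot_set:
  - Val882
  - Lys833
  - Tyr867
  - Asp964
  - Asp836
  - Thr886
  - Thr887
  - Met953
  - Ile963
hot_require: any
hot_itypes: hbond
max_lipinski_violations: 0
seed: 1
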
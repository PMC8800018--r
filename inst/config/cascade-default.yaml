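# Full-scale sequential screening profile: a ~2,000,000-compound library
# triaged to 10,000 by ensemble docking rank, 2,000 by Bayesian consensus
# score, 200 drug-like, 100 scaffold-diverse, 49 with hot-residue contacts.
dock_keep: 10000
bayes_keep: 2000
druglike_keep: 200
diversity_keep: 100
final_keep: 49
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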
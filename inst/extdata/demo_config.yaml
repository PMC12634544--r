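# Demonstration pipeline configuration: everything synthetic, seeded.
# Soil and enzyme variables use the bundled generating parameters
# (soil_table_params.tsv). The micronutrient generating parameters below are
# SYNTHETIC placeholders (plausible mg/kg magnitudes with treatment trends);
# no measured values for them are bundled with the package.
seed: 42
n_replicates: 3
alpha: 0.05
permutations: 999
rho_min: 0.6
q_max: 0.01
# 199 permutations: with the pooled null, the smallest attainable BH q is
# about 1/B, so B must exceed 100 for the q < 0.01 rule to be reachable
network_permutations: 199
n_boot: 200
stoich_mode: literal
communities:
  bacteria:
    n_taxa: 120
    read_depth: 3000
    log_mean_range: [4, -4]
    correlated_pairs:
      - {a: 3, b: 7, rho: 0.9}
      - {a: 6, b: 15, rho: 0.85}
      - {a: 9, b: 20, rho: -0.8}
    fold_changes:
      B2: {taxon_002: 2.5, taxon_010: 2.0}
      B3: {taxon_001: 0.3, taxon_005: 4.0, taxon_012: 3.0}
      B4: {taxon_001: 0.3, taxon_005: 5.0, taxon_012: 3.5}
  fungi:
    n_taxa: 80
    read_depth: 3000
    log_mean_range: [4, -4]
    correlated_pairs:
      - {a: 2, b: 5, rho: 0.9}
      - {a: 8, b: 11, rho: 0.85}
    fold_changes:
      B2: {taxon_003: 3.0}
      B3: {taxon_001: 4.0, taxon_004: 0.2}
      B4: {taxon_001: 5.0, taxon_004: 0.1}
extra_variables:
  - variable: Mg
    unit: mg/kg
    means: {B1: 310, B2: 305, B3: 325, B4: 330}
    sds:   {B1: 12,  B2: 12,  B3: 12,  B4: 12}
  - variable: Fe
    unit: mg/kg
    means: {B1: 152, B2: 150, B3: 158, B4: 161}
    sds:   {B1: 7,   B2: 7,   B3: 7,   B4: 7}
  - variable: Mn
    unit: mg/kg
    means: {B1: 25,  B2: 21,  B3: 38,  B4: 46}
    sds:   {B1: 2,   B2: 2,   B3: 3,   B4: 3}
  - variable: Cu
    unit: mg/kg
    means: {B1: 3.2, B2: 2.6, B3: 2.9, B4: 3.0}
    sds:   {B1: 0.2, B2: 0.2, B3: 0.2, B4: 0.2}
  - variable: Zn
    unit: mg/kg
    means: {B1: 8.4, B2: 7.6, B3: 8.9, B4: 9.4}
    sds:   {B1: 0.4, B2: 0.4, B3: 0.4, B4: 0.4}
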
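# Baseline model for uncatalyzed RNA phosphodiester transesterification.
#
# k_ref_per_s is the background cleavage rate at the reference condition
# (310.15 K, pH 7.5, 150 mM monovalent, 1 mM Mg2+), an approximate
# transcription of published measurements of spontaneous RNA cleavage.
# Every cross-construct activation-energy *difference* is independent of this
# absolute value; it only shifts the ledger's common offset.
#
# Coefficients (parameterized mode):
#   ph_slope  - decades of rate per pH unit in the base-catalyzed regime
#               (first order in hydroxide)
#   ph_min    - pH below which the rate stops decreasing (pH-independent floor)
#   ea_uncat  - Arrhenius activation energy of background cleavage, kcal/mol
#   mg_alpha  - linear divalent-ion acceleration, per mM Mg2+
mode: parameterized
k_ref_per_s: 1.7e-10
coefficients:
  ph_ref: 7.5
  ph_min: 6.0
  ph_slope: 1.0
  temp_ref: 310.15
  ea_uncat: 29.9
  mg_alpha: 0.7
  mg_ref: 1.0
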
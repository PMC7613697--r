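# Country-override rules for composition resolution. Rules are data: adding
# or editing an override needs no code change.
#
# blend:   for domestically retained flows in the listed countries, the
#          resolved record is blend_share * blend_fc + (1 - blend_share) * base;
#          exports and imports always use the base (refined) record.
# replace: the listed countries always use replacement_fc for this category.
rules:
  - type: blend
    fc_code: palm_oil
    blend_fc: palm_oil_red      # unrefined red palm oil, carotenoid-rich
    blend_share: 0.70           # share of domestically retained palm oil consumed unrefined
    countries:                  # tropical rain-belt Sub-Saharan Africa
      [NGA, GHA, CIV, CMR, COD, COG, GAB, GNQ, LBR, SLE, GIN, BEN, TGO, UGA, CAF, STP]
  - type: replace
    fc_code: rice
    replacement_fc: rice_parboiled   # parboiled, polished white rice
    countries: [BGD]
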
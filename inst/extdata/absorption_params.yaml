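# Mineral absorption parameters.
# Coefficients are transcribed from the cited publications; edit with care and
# keep the citation strings in step. All diet covariates are per-capita daily
# amounts: mg for iron, phytate, calcium, vitamin C and polyphenols
# (tannic-acid equivalents), g for meat+fish+poultry (MFP).
version: 1
heme:
  heme_fraction: 0.40          # share of iron in heme-source foods counted as heme
  heme_bioavailability: 0.25   # assumed absorption of heme iron
serum_ferritin_ref: 21.7       # mcg/L, reference corresponding to 40% dose absorption
clamp: [0.001, 1.0]            # absorption fraction bounds applied to all algorithms

iron_algorithms:
  conway:
    citation: "Conway et al. (2007), food group-based regression for dietary nonheme iron absorption"
    link: identity               # terms sum directly to percent absorption
    intercept: 9.64
    terms:
      - {var: vitamin_c, transform: linear, coef: 0.045}
      - {var: mfp, transform: linear, coef: 0.042}
      - {var: phytate, transform: linear, coef: -0.0037}
      - {var: calcium, transform: linear, coef: -0.0016}
  rickard:
    citation: "Rickard et al. (2009), test-meal algorithm with log-transformed enhancer/inhibitor terms"
    link: exp                    # exp(sum) gives percent absorption
    intercept: 2.162
    terms:
      - {var: vitamin_c, transform: log1p, coef: 0.094}
      - {var: mfp, transform: log1p, coef: 0.135}
      - {var: phytate, transform: log1p, coef: -0.231}
      - {var: polyphenols, transform: log1p, coef: -0.067}
      - {var: calcium, transform: log1p, coef: -0.052}
  armah:
    citation: "Armah et al. (2013), complete-diet log-linear model anchored on serum ferritin"
    link: exp
    intercept: 6.294
    terms:
      - {var: serum_ferritin, transform: log, coef: -0.709}
      - {var: vitamin_c, transform: log, coef: 0.119, offset: 0.05}
      - {var: mfp, transform: linear, coef: 0.006}
      - {var: polyphenols, transform: linear, coef: -0.0003}
      - {var: phytate, transform: log, coef: -0.247, offset: 0.05}
      - {var: calcium, transform: log, coef: -0.137, offset: 0.05}
      - {var: nonheme_iron, transform: log, coef: -0.083, offset: 0.05}

zinc:
  citation: "Updated trivariate saturable-absorption model of zinc absorption (Miller/Hambidge), constants in mmol/day"
  amax: 0.091   # maximal absorbed zinc, mmol/day
  kr: 0.033     # redistribution (dissociation) constant, mmol/day
  kp: 0.680     # zinc-phytate binding constant, mmol/day
  molar_mass_zinc: 65.38      # g/mol
  molar_mass_phytate: 660.04  # g/mol (inositol hexaphosphate)
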
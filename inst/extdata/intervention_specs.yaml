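# Vitamin A capsule doses and wheat-flour fortificant specifications.
capsules:
  d100k_mcg: 30000     # 100,000 IU capsule, mcg retinol
  d200k_mcg: 60000     # 200,000 IU capsule, mcg retinol
  protocol:
    infants_6_11_months: 1   # capsules/year
    children_1_4_years: 2
fortificants:
  vitamin_a:
    nutrient: vitamin_a_mcg
    level_mg_per_kg: 3        # retinol
    bioavailability: 1.0
    deficit_unit: mcg
  iron:
    nutrient: iron_mg
    level_mg_per_kg: 35       # sodium-iron EDTA (NaFeEDTA)
    bioavailability: 0.10
    deficit_unit: mg
  zinc:
    nutrient: zinc_mg
    level_mg_per_kg: 30       # zinc oxide
    bioavailability: 0.30
    deficit_unit: mg
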
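nutrient,year,n_deficit_countries,aggregate_intake_per_day,aggregate_requirement_per_day,annual_deficit,deficit_unit,annual_deficit_scale,annual_flour_consumed_1000mt
vitamin_a,1961,105,382,895,187200,mcg,1e9,46902
vitamin_a,2018,90,1221,1840,225870,mcg,1e9,185211
iron,1961,156,1947,2820,318588,mg,1e6,94931
iron,2018,129,4136,5317,431072,mg,1e6,251657
zinc,1961,115,4113,5374,460101,mg,1e6,47484
zinc,2018,111,13256,15679,884438,mg,1e6,253586
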
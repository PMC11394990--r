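"category","per_capita"
"dairy_products",21.93
"starch_products",1.9
"grain_processing_products",9.9
"meat_products",8.04
"soy_products",25.12
"edible_agricultural_products",2.49
"edible_oil_products",11.64
"catering_food",7.54
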
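"city","region"
"city_A","region_X"
"city_B","region_X"
"city_C","region_X"
"city_D","region_X"
"city_E","region_X"
"city_F","region_X"
"city_G","region_X"
"city_H","region_X"
"city_I","region_X"
"city_J","region_X"
"city_K","region_X"
"city_L","region_X"
"city_M","region_X"
"city_N","region_X"
"city_O","region_X"
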
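"channel_name","size_class"
"supermarket","medium"
"shopping_mall","large"
"vegetable_market","small"
"wholesale_market","large"
"farm_product_market","large"
"convenience_store","small"
"grocery_store","small"
"snack_bar","large"
"fast_food","large"
"restaurant","medium"
"canteen","small"
"online_shop","large"
"specialty_store","small"
"street_vendor","small"
"food_stall","large"
"bakery","medium"
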
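food_group,category,classification,serving_size_g_edible,servings_per_week,g_per_week,green_per_kg,blue_per_kg,grey_per_kg,total_per_kg,week_green,week_blue,week_grey,week_total,note
fruit_vegetables,Green vegetables,plant,60,1.5,133,170,60,96,325,23,6,12,41,
fruit_vegetables,Red and orange vegetables,plant,145,5.5,916,201,32,68,301,184,30,62,276,
fruit_vegetables,Starchy vegetables,plant,161,5,944,757,49,113,918,744,43,97,884,weekly cells serving-weighted; not mass x printed WF/kg
fruit_vegetables,Other vegetables,plant,112,4,563,292,76,206,574,164,43,116,323,
pulses,Dry pulses,plant,74,1.5,111,3174,218,879,4271,352,24,98,474,
fruit_vegetables,Fruit,plant,161,14,3175,458,141,92,690,1372,424,266,2062,weekly cells serving-weighted; not mass x printed WF/kg
cereals,Whole grains,plant,28,21,588,2059,254,150,2463,1211,149,88,1448,
cereals,Refined grains,plant,28,21,588,1531,351,211,2093,900,206,124,1230,
dairy,Dairy,animal,115,21,2408,3130,321,262,3713,4459,454,373,5284,cup-equivalent serving-weighted; not mass x printed WF/kg
meat_eggs_seafood,"Meat, poultry, eggs",animal,34,26,964,6365,392,492,7248,5550,354,465,6369,weekly cells serving-weighted; not mass x printed WF/kg
meat_eggs_seafood,Seafood,animal,28,8,320,815,90,83,987,261,29,27,316,g/week is half of suggested consumption (50% aquaculture)
fruit_vegetables,"Nuts, seeds, soy products",plant,19,5,96,5200,2724,1034,8958,426,193,73,692,weekly cells serving-weighted; not mass x printed WF/kg
oils,Oils,plant,27,7,189,3603,288,355,4246,681,54,67,802,
indulgence,Limit on calories for other use (240 kcal/day),other,260,7,1823,749,224,152,1127,882,193,161,1238,weekly cells serving-weighted; not mass x printed WF/kg
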
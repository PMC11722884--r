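food_group,category,classification,serving_size_g_edible,servings_per_week,g_per_week,green_per_kg,blue_per_kg,grey_per_kg,total_per_kg,week_green,week_blue,week_grey,week_total,note
meat_eggs_seafood,Red meat,animal,100,1,113,9661,505,537,10702,1092,57,61,1209,
meat_eggs_seafood,White meat,animal,100,2,286,3545,313,467,4325,1014,90,134,1237,
meat_eggs_seafood,Fish/seafood,animal,150,2,428,815,90,83,987,349,38,36,422,
meat_eggs_seafood,Processed fish,animal,50,1,50,815,90,83,987,41,4,4,49,
meat_eggs_seafood,Eggs,animal,50,3,172.5,2592,244,429,3265,447,42,74,563,
dairy,Milk/yoghurt,animal,125,21,2625,863,86,72,1020,2265,226,189,2678,
dairy,Soft cheese,animal,100,2,200,4264,439,357,5060,853,88,71,1012,
dairy,Hard cheese,animal,50,1,50,4264,439,357,5060,213,22,18,253,
cereals,Bread,plant,50,24.5,1225,1124,301,183,1608,1377,369,224,1970,
cereals,Bread analogue,plant,80,10.5,840,1562,322,223,2108,1312,270,188,1770,
cereals,"Pasta, rice, barley",plant,30,1,30,1126,322,113,1608,34,10,3,48,per-kg components sum to 1561 not 1608
cereals,Sweet bakery (croissants),plant,50,1,50,2843,812,284,4062,142,41,14,203,per-kg components sum to 3939 not 4062
cereals,Sweet bakery (biscuits),plant,30,1,30,2140,611,214,3057,64,18,6,92,per-kg components sum to 2965 not 3057
cereals,Breakfast cereals,plant,30,2,60,1998,245,173,2416,120,15,10,145,
cereals,Potatoes,plant,200,2,482,191,33,63,287,92,16,30,138,
pulses,Dry pulses,plant,50,3,150,3174,218,879,4271,476,33,132,641,
oils,Vegetable oil,plant,10,14,140,7994,1324,313,9631,1119,185,44,1348,
oils,Butter,plant,10,7,70,4965,465,393,5553,348,33,28,389,per-kg components sum to 5823 not 5553
fruit_vegetables,Fresh fruit,plant,150,21,4074,540,171,108,819,2200,695,441,3337,
fruit_vegetables,Nuts (shelled),plant,30,2,60,5761,3253,1231,10245,346,195,74,615,
fruit_vegetables,Leafy vegetables,plant,200,10.5,2919,239,69,94,402,698,201,274,1173,
fruit_vegetables,Other vegetables,plant,80,7,742,147,21,104,271,109,16,77,201,
indulgence,Sugar,other,5,10.5,52.5,860,327,137,1324,45,17,7,70,
indulgence,Jam,other,20,2,40,1277,416,321,2018,51,17,13,81,printed jam WF/kg not reproducible from the 35% fruit / 40% sugar rule
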
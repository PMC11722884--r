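food_group,category,classification,serving_size_g_edible,servings_per_week,g_per_week,green_per_kg,blue_per_kg,grey_per_kg,total_per_kg,week_green,week_blue,week_grey,week_total,note
cereals,Cereals and potatoes,plant,79,27,2336,1204,252,166,1621,2118,458,325,2902,weekly cells serving-weighted; not mass x printed WF/kg
fruit_vegetables,Fruit,plant,175,19,4350,412,112,95,618,1793,486,412,2691,
fruit_vegetables,Vegetables,plant,200,13,3061,189,38,103,327,579,118,316,1003,weekly component cells sum to 1013 not 1003
oils,Extra virgin olive oil,plant,14,19,261,11826,2388,217,14431,3089,624,57,3769,
dairy,Dairy,animal,125,13,1664,2564,263,215,3040,4829,493,404,5724,serving-weighted milk/cheese average; not mass x printed WF/kg
meat_eggs_seafood,Seafood,animal,125,3,476,815,90,83,987,387,43,39,469,
meat_eggs_seafood,White meat,animal,125,2,317,3545,313,467,4325,1124,99,148,1371,
meat_eggs_seafood,Red meat,animal,125,0.4,53,14414,550,451,15415,762,29,24,815,
meat_eggs_seafood,Eggs,animal,58,3,255,503,47,83,633,503,47,83,634,printed weekly cells identical to WF/kg cells; carried as printed
pulses,Dry Pulses,plant,70,2,160,3174,218,879,4271,508,35,141,683,
fruit_vegetables,Nuts,plant,25,4,95,5761,3253,1231,10245,548,310,117,975,
indulgence,Sugar,other,5,10.5,52.5,858,327,137,1324,45,17,7,69,printed g/week 1668 inconsistent with its own weekly WF; serving math 52.5 g used
indulgence,Jam,other,20,2,40,1277,416,321,2018,51,17,13,81,
indulgence,Wine/beer,other,150,10.5,1575,431,77,76,584,585,89,93,769,weekly cells per-member serving-weighted; not mass x printed WF/kg
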
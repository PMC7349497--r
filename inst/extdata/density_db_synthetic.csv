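food_id,density_g_per_cm3,kcal_per_g,carb_g_per_g,protein_g_per_g,sugar_g_per_g,fat_g_per_g
mashed_potatoes,1.03,1.13,0.17,0.02,0.014,0.042
meatloaf,1.05,2.04,0.06,0.14,0.021,0.132
chicken_breast,1.04,1.65,0.00,0.31,0.000,0.036
roasted_vegetables,0.61,0.93,0.13,0.02,0.045,0.041
garlic_pasta,0.55,1.57,0.26,0.06,0.019,0.038
apple,0.84,0.52,0.14,0.003,0.104,0.002
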
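group,variable,value,unit
FS_ACCEPTABLE,n,1003,individuals
FS_EXCESS,n,690,individuals
ALL,n,1693,individuals
FS_ACCEPTABLE,energy,2123,kcal/day
FS_EXCESS,energy,2192,kcal/day
FS_ACCEPTABLE,energy_main_meals,1992,kcal/day
FS_EXCESS,energy_main_meals,1935,kcal/day
FS_ACCEPTABLE,energy_snacking,131,kcal/day
FS_EXCESS,energy_snacking,258,kcal/day
FS_ACCEPTABLE,free_sugars_pct_energy,6.3,% energy
FS_EXCESS,free_sugars_pct_energy,14.2,% energy
FS_ACCEPTABLE,free_sugars,33.5,g/day
FS_EXCESS,free_sugars,78.7,g/day
FS_ACCEPTABLE,free_sugars_main_meals,27.2,g/day
FS_EXCESS,free_sugars_main_meals,57.0,g/day
FS_ACCEPTABLE,free_sugars_snacking,6.3,g/day
FS_EXCESS,free_sugars_snacking,21.7,g/day
FS_ACCEPTABLE,meal_snack_fs_ratio_printed,4.3,ratio
FS_EXCESS,meal_snack_fs_ratio_printed,2.6,ratio
FS_ACCEPTABLE,delta_free_sugars,-1.2,g/day
FS_ACCEPTABLE,delta_non_free_sugars,18.7,g/day
FS_ACCEPTABLE,delta_total_sugars_printed,17.5,g/day
FS_EXCESS,delta_free_sugars,-25.5,g/day
FS_EXCESS,delta_non_free_sugars,22.1,g/day
FS_EXCESS,delta_total_sugars_printed,-3.4,g/day
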
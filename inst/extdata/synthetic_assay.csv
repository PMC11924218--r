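"sample_id","droplet_id","droplet_volume_uL","dilution_factor","freeze_temp_C","treatment","background_id"
"T-striatum-like",1,1,1,-12.5,"none",""
"T-striatum-like",2,1,1,-19.5,"none",""
"T-striatum-like",3,1,1,-19,"none",""
"T-striatum-like",4,1,1,-12.5,"none",""
"T-striatum-like",5,1,1,-12.5,"none",""
"T-striatum-like",6,1,1,-13.5,"none",""
"T-striatum-like",7,1,1,-16.5,"none",""
"T-striatum-like",8,1,1,-15.5,"none",""
"T-striatum-like",9,1,1,-18.5,"none",""
"T-striatum-like",10,1,1,-16.5,"none",""
"T-striatum-like",11,1,1,-14.5,"none",""
"T-striatum-like",12,1,1,-12.5,"none",""
"T-striatum-like",13,1,1,-24,"none",""
"T-striatum-like",14,1,1,-14.5,"none",""
"T-striatum-like",15,1,1,-12.5,"none",""
"T-striatum-like",16,1,1,-19,"none",""
"T-striatum-like",17,1,1,-18.5,"none",""
"T-striatum-like",18,1,1,-17,"none",""
"T-striatum-like",19,1,1,-12.5,"none",""
"T-striatum-like",20,1,1,-13,"none",""
"T-striatum-like",21,1,1,-15,"none",""
"T-striatum-like",22,1,1,-16,"none",""
"T-striatum-like",23,1,1,-15,"none",""
"T-striatum-like",24,1,1,-18.5,"none",""
"T-striatum-like",25,1,1,-20,"none",""
"T-striatum-like",26,1,1,-17,"none",""
"T-striatum-like",27,1,1,-17.5,"none",""
"T-striatum-like",28,1,1,-17.5,"none",""
"T-striatum-like",29,1,1,-20,"none",""
"T-striatum-like",30,1,1,-16.5,"none",""
"T-striatum-like",31,1,1,-16,"none",""
"T-striatum-like",32,1,1,-17,"none",""
"T-striatum-like",33,1,1,-11,"none",""
"T-striatum-like",34,1,1,-18,"none",""
"T-striatum-like",35,1,1,-19,"none",""
"T-striatum-like",36,1,1,-20,"none",""
"T-striatum-like",37,1,1,-22,"none",""
"T-striatum-like",38,1,1,-13,"none",""
"T-striatum-like",39,1,1,-15.5,"none",""
"T-striatum-like",40,1,1,-14,"none",""
"T-striatum-like",41,1,1,-18,"none",""
"T-striatum-like",42,1,1,-18.5,"none",""
"T-striatum-like",43,1,1,-11,"none",""
"T-striatum-like",44,1,1,-17,"none",""
"T-striatum-like",45,1,1,-15,"none",""
"T-striatum-like",46,1,1,-9,"none",""
"T-striatum-like",47,1,1,-17,"none",""
"T-striatum-like",48,1,1,-15,"none",""
"T-striatum-like",49,1,1,-17,"none",""
"T-striatum-like",50,1,1,-14,"none",""
"T-striatum-like",51,1,1,-15,"none",""
"T-striatum-like",52,1,1,-16,"none",""
"T-striatum-like",53,1,1,-15,"none",""
"T-striatum-like",54,1,1,-20.5,"none",""
"T-striatum-like",55,1,1,-14.5,"none",""
"T-striatum-like",56,1,1,-13,"none",""
"T-striatum-like",57,1,1,-14,"none",""
"T-striatum-like",58,1,1,-19,"none",""
"T-striatum-like",59,1,1,-16,"none",""
"T-striatum-like",60,1,1,-12.5,"none",""
"T-striatum-like",1,1,10,-19,"none",""
"T-striatum-like",2,1,10,-20.5,"none",""
"T-striatum-like",3,1,10,-24,"none",""
"T-striatum-like",4,1,10,-24.5,"none",""
"T-striatum-like",5,1,10,-23,"none",""
"T-striatum-like",6,1,10,-20.5,"none",""
"T-striatum-like",7,1,10,-29,"none",""
"T-striatum-like",8,1,10,-22,"none",""
"T-striatum-like",9,1,10,-26,"none",""
"T-striatum-like",10,1,10,-24.5,"none",""
"T-striatum-like",11,1,10,-18.5,"none",""
"T-striatum-like",12,1,10,-23,"none",""
"T-striatum-like",13,1,10,-30.5,"none",""
"T-striatum-like",14,1,10,-29,"none",""
"T-striatum-like",15,1,10,-26.5,"none",""
"T-striatum-like",16,1,10,-27.5,"none",""
"T-striatum-like",17,1,10,-19.5,"none",""
"T-striatum-like",18,1,10,-19,"none",""
"T-striatum-like",19,1,10,-21,"none",""
"T-striatum-like",20,1,10,-26,"none",""
"T-striatum-like",21,1,10,-25.5,"none",""
"T-striatum-like",22,1,10,-26,"none",""
"T-striatum-like",23,1,10,-12.5,"none",""
"T-striatum-like",24,1,10,-21,"none",""
"T-striatum-like",25,1,10,-22.5,"none",""
"T-striatum-like",26,1,10,-29,"none",""
"T-striatum-like",27,1,10,-24.5,"none",""
"T-striatum-like",28,1,10,-22,"none",""
"T-striatum-like",29,1,10,-22,"none",""
"T-striatum-like",30,1,10,-22.5,"none",""
"T-striatum-like",31,1,10,-15,"none",""
"T-striatum-like",32,1,10,-10.5,"none",""
"T-striatum-like",33,1,10,-20.5,"none",""
"T-striatum-like",34,1,10,-23.5,"none",""
"T-striatum-like",35,1,10,-15,"none",""
"T-striatum-like",36,1,10,-28.5,"none",""
"T-striatum-like",37,1,10,-25,"none",""
"T-striatum-like",38,1,10,-25.5,"none",""
"T-striatum-like",39,1,10,-28.5,"none",""
"T-striatum-like",40,1,10,-21,"none",""
"T-striatum-like",41,1,10,-20.5,"none",""
"T-striatum-like",42,1,10,-25,"none",""
"T-striatum-like",43,1,10,-21,"none",""
"T-striatum-like",44,1,10,-23.5,"none",""
"T-striatum-like",45,1,10,-17.5,"none",""
"T-striatum-like",46,1,10,-26,"none",""
"T-striatum-like",47,1,10,-21,"none",""
"T-striatum-like",48,1,10,-15.5,"none",""
"T-striatum-like",49,1,10,-15,"none",""
"T-striatum-like",50,1,10,-20.5,"none",""
"T-striatum-like",51,1,10,-17,"none",""
"T-striatum-like",52,1,10,-24,"none",""
"T-striatum-like",53,1,10,-25.5,"none",""
"T-striatum-like",54,1,10,-21.5,"none",""
"T-striatum-like",55,1,10,-20.5,"none",""
"T-striatum-like",56,1,10,-22.5,"none",""
"T-striatum-like",57,1,10,-20,"none",""
"T-striatum-like",58,1,10,-19.5,"none",""
"T-striatum-like",59,1,10,-21.5,"none",""
"T-striatum-like",60,1,10,-22,"none",""
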
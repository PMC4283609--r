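assemblage_id,latitude,longitude,paleolatitude,elevation_m,biome,epoch
La Venta,3.2,-75.2,2.6,380,tropical,middle_miocene
Fitzcarrald,-10.5,-72.7,-12,300,tropical,middle_miocene
Quebrada Honda,-22,-65,-22.3,3500,temperate,middle_miocene
Collon Cura,-40,-70.2,-41.3,800,temperate,middle_miocene
Urumaco,11,-70.3,10.9,100,tropical,late_miocene
Acre,-10,-70,-10.5,300,tropical,late_miocene
Mesopotamian,-32,-60.5,-32.5,100,temperate,late_miocene
Cerro Azul,-37,-64.5,-37,150,temperate,late_miocene
Chiquimil,-27,-66,-27,1750,temperate,late_miocene
Andalhuala,-27,-66.2,-26.8,1750,temperate,late_miocene
Monte Hermoso,-38,-61.7,-38.9,100,temperate,late_miocene
Inchasi,-19,-65.4,-19.9,3220,temperate,pliocene
Uquia,-23,-65.4,-23.4,2800,temperate,pliocene
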
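biome_id,modern_km2,modern_pct,high_mitigation_km2,high_mitigation_pct,low_mitigation_km2,low_mitigation_pct
tropical evergreen forest,817813,20.14,842705,24.20,1317980,21.56
tropical deciduous forest,604130,14.88,558277,16.03,766776,12.54
tropical grassland/shrubland/savanna,2010784,49.52,1372585,39.42,2281542,37.31
temperate deciduous forest,44004,1.08,49132,1.41,121593,1.99
temperate grassland/shrubland/savanna,135381,3.33,219644,6.31,259302,4.24
conifer and mixed forest,395355,9.74,394149,11.32,1284318,21.00
montane taiga evergreen forest,12337,0.30,23794,0.68,36973,0.60
montane taiga deciduous forest,38160,0.94,19254,0.55,31589,0.52
tundra,2795,0.07,2413,0.07,14355,0.23
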
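app,flower,fruit,leaf,plant,herb,monocot,woody,average
Plant.id,76,67,62,71,65,66,92,69.8
Google Lens,69,70,58,61,56,70,83,63.4
Seek,56,79,51,68,63,51,63,60.7
Flora Incognita,67,33,48,56,52,61,61,60.3
PlantNet,58,73,42,50,49,50,65,52.1
PlantSnap,42,47,31,43,38,31,53,39.7
Candide,29,1,19,29,23,37,17,24.3
Bing,17,18,8,22,19,12,12,16.3
iPlant,12,26,11,14,7,18,30,13.4
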
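app,flower,fruit,leaf,plant,herb,monocot,woody
Plant.id,1,4,1,1,1,2,1
Google Lens,2,3,2,3,3,1,2
Seek,5,1,3,2,2,4,4
Flora Incognita,3,6,4,4,4,3,5
PlantNet,4,2,5,5,5,5,3
PlantSnap,6,5,6,6,6,7,6
Candide,7,9,7,7,7,6,8
Bing,8,8,9,8,8,9,9
iPlant,9,7,8,9,9,8,7
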
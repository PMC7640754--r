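app,flower,fruit,leaf,plant,herb,monocot,woody,average
Seek,3.3,3.5,3.4,3.5,3.6,2.6,3.6,3.4
Plant.id,3.4,3.3,3.2,2.9,3.0,3.3,3.7,3.2
Flora Incognita,3.5,2.3,2.8,3.0,2.9,3.3,3.3,3.0
Google Lens,3.1,2.7,3.1,2.7,2.8,3.1,3.1,2.9
PlantNet,2.7,2.7,2.4,2.2,2.4,2.5,2.4,2.5
PlantSnap,2.1,2.3,2.0,2.2,2.0,2.1,2.7,2.1
iPlant,2.3,2.6,2.2,1.7,2.0,2.1,2.4,2.1
Candide,2.1,0.7,1.1,1.8,1.6,2.3,0.8,1.6
Bing,1.4,1.3,1.0,1.5,1.5,1.5,0.6,1.3
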
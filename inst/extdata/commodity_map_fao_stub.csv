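raw,group
Wheat,grains
Maize (corn),grains
Rice,grains
Millet,grains
Sorghum,grains
Potatoes,roots and tubers
Cassava fresh,roots and tubers
Sweet potatoes,roots and tubers
Tomatoes,vegetables
Onions and shallots dry (excluding dehydrated),vegetables
Bananas,fruits
Mangoes guavas and mangosteens,fruits
Beans dry,pulses
Lentils dry,pulses
Meat of chickens fresh or chilled,meat products
Meat of cattle with the bone fresh or chilled,meat products
Raw milk of cattle,dairy and eggs
Hen eggs in shell fresh,dairy and eggs
Soya beans,oilseeds
Groundnuts excluding shelled,oilseeds
Sugar cane,sugar products
Coffee green,beverages
Tea leaves,beverages
Spices nes,others
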
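raw,group
wheat,grains
maize,grains
rice,grains
barley,grains
potatoes,roots and tubers
cassava,roots and tubers
yams,roots and tubers
tomatoes,vegetables
onions,vegetables
cabbages,vegetables
bananas,fruits
apples,fruits
oranges,fruits
beans,pulses
lentils,pulses
chickpeas,pulses
poultry meat,meat products
bovine meat,meat products
pig meat,meat products
milk,dairy and eggs
eggs,dairy and eggs
cheese,dairy and eggs
soybeans,oilseeds
sunflower seed,oilseeds
rapeseed,oilseeds
sugar cane,sugar products
sugar beet,sugar products
coffee,beverages
tea,beverages
cocoa beans,beverages
spices,others
honey,others
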
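source_name,canonical_name,provenance
"Korea, Rep.",Republic of Korea,worldbank
"Korea, Republic of",Republic of Korea,fao
"Egypt, Arab Rep.",Egypt,worldbank
"Iran, Islamic Rep.",Iran,worldbank
"Iran (Islamic Republic of)",Iran,fao
Viet Nam,Vietnam,fao
"Venezuela, RB",Venezuela,worldbank
Venezuela (Bolivarian Republic of),Venezuela,fao
Russian Federation,Russia,worldbank
United Republic of Tanzania,Tanzania,fao
"Tanzania, United Rep.",Tanzania,worldbank
Bolivia (Plurinational State of),Bolivia,fao
"Congo, Dem. Rep.",Democratic Republic of the Congo,worldbank
Lao PDR,Laos,worldbank
Lao People's Democratic Republic,Laos,fao
Syrian Arab Republic,Syria,worldbank
Turkiye,Turkey,worldbank
"Gambia, The",Gambia,worldbank
Cote d'Ivoire,Ivory Coast,worldbank
Côte d'Ivoire,Ivory Coast,fao
United States of America,United States,fao
United Kingdom of Great Britain and Northern Ireland,United Kingdom,fao
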
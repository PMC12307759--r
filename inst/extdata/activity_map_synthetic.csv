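raw,group
harvesting,harvest and on-farm operations
threshing,harvest and on-farm operations
on-farm handling,harvest and on-farm operations
milling,processing
processing,processing
canning,processing
transport,transport and distribution
distribution,transport and distribution
loading,transport and distribution
storage,storage
warehousing,storage
retail,marketing and retail
wholesale,marketing and retail
marketing,marketing and retail
household consumption,consumption
food service,consumption
packaging,packaging
packing,packaging
unspecified,others
whole supply chain,others
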
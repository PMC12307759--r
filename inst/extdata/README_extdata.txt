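Shipped data files
==================

commodity_map_synthetic.csv, activity_map_synthetic.csv
  Raw-label -> analysis-group maps covering the vocabulary emitted by the
  package's synthetic FLP generator. Category maps are data, not code, so
  they stay auditable and swappable.

commodity_map_fao_stub.csv
  A deliberately incomplete STUB of an FAO-style commodity map. It exists
  only to show the expected file shape for real FAO labels; any real
  analysis must supply its own complete, audited map.

country_harmonization_synthetic.csv
  A best-effort, SYNTHETIC stand-in harmonization table mapping a few
  common World Bank / FAO country-name spellings to canonical display
  names. It is illustrative, not an authoritative record of any study's
  harmonization decisions; users should edit or replace it.
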
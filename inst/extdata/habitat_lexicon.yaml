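# Controlled vocabulary for habitat water-availability classification.
# `wet` terms take precedence over `arid` soil terms; anything else is
# `intermediate`. Edit and pass via classify_habitat(lexicon = ...).
wet:
  - wetland
  - wetlands
  - bog
  - bogs
  - swamp
  - swamps
  - marsh
  - marshes
  - river
  - rivers
  - riverbank
  - stream
  - streams
  - lake
  - lakes
  - pond
  - ponds
  - water body
  - water bodies
arid:
  - sandy
  - sand
  - stony
  - stone
  - gravelly
  - gravel
  - rocky
  - rocks
  - well-drained
water_score:
  Hydrophyte: 5
  Helophyte: 4
  Mesophyte: 3
  Xerophyte: 1
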
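# Functional-guild taxonomy patterns (case-insensitive substrings matched
# against the full semicolon-delimited lineage string). A taxon is assigned
# to the FIRST matching guild, so narrower guilds must come first: ANME
# clades nest inside the methanogenic order Methanosarcinales. This is a
# best-effort clade inventory and is meant to be edited.
ANME:
  - ANME
aerobic_methanotroph:
  - Methylococcaceae
  - Methylocystaceae
  - Methylomonas
  - Methylobacter
  - Methylosinus
  - Methylocella
  - Crenotrichaceae
methanogen:
  - Methanobacteriales
  - Methanococcales
  - Methanomicrobiales
  - Methanosarcinales
  - Methanocellales
  - Methanopyrales
  - Methanomassiliicoccales
  - Methanofastidiosa
  - Methanoregula
  - Methanosaeta
  - Methanothrix
syntrophaceae:
  - Syntrophaceae
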
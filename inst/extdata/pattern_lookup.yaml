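# Arrangement pattern lookups (editable data, not code).
#
# hox Groups 4-6 are only described collectively in the source
# classification (hoxE/hoxF co-clustered, remaining genes clustered or
# scattered "in various combinations"); the per-signature assignments
# below are the package's placeholder enumeration and can be replaced to
# match any published drawing. Likewise the hup group numbers attach to
# the two distinguishing axes (hupW location x xisC interruption); only
# the axes themselves are canonical.
hox:
  EF+UY+H+W: G4
  UYH+EF+W: G5
  EF+H+U+W+Y: G6
hup:
  clustered|none: G1
  distal|none: G2
  clustered|hupL: G3
  distal|hupL: G4
  clustered|hupS: G5
  distal|hupS: G5
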
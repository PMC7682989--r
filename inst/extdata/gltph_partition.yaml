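# Curator-derived domain partition for the GltPh aspartate transporter,
# author residue numbering (inclusive ranges), assembled from the
# secondary-structure annotation of the deposited inward- and outward-facing
# models. The scaffold (trimerization) domain comprises TM1, TM2, TM4(a-c)
# and TM5; the transport domain comprises TM3, TM6, TM7, HP1, HP2 and TM8.
# Boundaries are approximate at the level of inter-helix loops; override
# with a custom file for sensitivity analysis.
sets:
  scaffold:
    - "12-84"
    - "122-212"
  transport:
    - "85-121"
    - "213-416"
  hp1:
    - "258-290"
  hp2:
    - "340-372"
  tm8a:
    - "373-390"
  hp2_tm8a_motif:
    - "340-390"
reference_residues:
  r276: 276        # HP1 tip arginine, cytoplasmic gate marker
  p356: 356        # HP2 tip proline, extracellular gate marker
  h37: 37          # TM1, extracellular membrane surface anchor
  k55: 55          # TM2, scaffold crosslink site
  a364: 364        # HP2 C-terminal arm / TM8a pivot region
  n_terminus_range: "1-11"   # amphipathic N-terminal helix, cytoplasmic surface
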
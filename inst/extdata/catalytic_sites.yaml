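# Catalytic-site specifications used by the site audits.
# Positions are 1-based in the ungapped reference sequence. Expected and
# loss sets list exact residues; conservative similarity does not count
# as conserved. The provenance field records how the homology call was
# made; it is metadata and never recomputed.
site_specs:
  - name: myce_methyltransferase
    reference_id: MycE
    provenance: >
      SAM/metal-dependent sugar methyltransferase; structure-informed
      alignment of the C-terminal catalytic domain; remote-homology
      confidence > 99%.
    sites:
      - position: 275   # Mg-coordinating aspartate
        expected: "D"
        loss: "N"
      - position: 304   # Mg-coordinating aspartate
        expected: "D"
        loss: "N"
      - position: 278   # histidine deprotonating the sugar 2-OH
        expected: "H"
        loss: ""
  - name: pglf_catalytic_asp
    reference_id: PglF
    provenance: >
      UDP-GlcNAc 4,6-dehydratase; the catalytic aspartate whose
      asparagine substitution abolishes activity.
    sites:
      - position: 396
        expected: "D"
        loss: "N"
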
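# Nucleotide-sugar biosynthetic pathway library for Megavirinae
# glycogenomics. Each step lists the reference query proteins whose
# conservation supports it (combined by max); site_spec names a
# catalytic-site specification whose loss flag marks the step impaired.
pathways:
  - name: UDP-l-Rha
    product: UDP-l-rhamnose
    clade: A
    steps:
      - role: "4,6-dehydratase"
        queries: [R141]
      - role: "3,5-epimerase/4-reductase"
        queries: [L780]
  - name: UDP-d-GlcNAc
    product: UDP-d-N-acetyl-glucosamine
    host_redundant: true
    steps:
      - role: glucosamine-6P synthase
        queries: [L619]
      - role: phosphoglucosamine mutase/acetyltransferase
        queries: [L316]
      - role: UDP-GlcNAc pyrophosphorylase
        queries: [R689]
  - name: UDP-d-2OMeVio4NAc
    product: UDP-d-2-O-methyl-4N-acetyl-viosamine
    clade: A
    steps:
      - role: "4,6-dehydratase"
        queries: [R141]
      - role: aminotransferase
        queries: [L136]
      - role: N-acetyltransferase
        queries: [L142]
      # methylation step; whether it acts on the UDP-sugar or the
      # polymerized glycan is left open, no ordering semantics implied
      - role: 2-O-methyltransferase
        queries: [R132]
        site_spec: myce_methyltransferase
  - name: UDP-l-Qui2NAc
    product: UDP-l-N-acetyl-quinovosamine (via UDP-l-Rha2NAc)
    steps:
      - role: "4,6-dehydratase/5-epimerase"
        queries: [Mg534, Ma458]
      - role: "4-reductase/3-epimerase"
        queries: [Mg535, Ma459]
      - role: "2-epimerase"
        queries: [Mg536, Ma460]
  - name: UDP-d-diNAcBac
    product: UDP-d-N,N'-diacetyl-bacillosamine
    steps:
      - role: "4,6-dehydratase"
        queries: [PglF, Ma467]
        site_spec: pglf_catalytic_asp
      - role: aminotransferase
        queries: [PglE, Ma465]
      - role: N-acetyltransferase
        queries: [PglD, Ma466]
  - name: UDP-d-Qui2N_Fuc2N
    product: UDP-d-N-acetyl-quinovosamine / UDP-d-N-acetyl-fucosamine
    steps:
      - role: "4,6-dehydratase"
        queries: [Mm422]
        site_spec: pglf_catalytic_asp
      - role: "4-reductase"
        queries: [Mm421, Mm419]
  - name: UDP-d-GlcA
    product: UDP-d-glucuronic acid
    steps:
      - role: UDP-glucose 6-dehydrogenase
        queries: [R520]
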
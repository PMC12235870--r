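# Allele model configuration for the Cs29/Cs6 translocation system.
# Coordinates are PLACEHOLDERS in ARS-UCD1.2-style space: replace the
# start/end values with lifted-over breakpoint coordinates before scoring
# real data. copies_added is the number of extra copies of the region
# contributed per carried allele.
wt: []
Cs29:
  - chrom: "6"
    start: 70000000
    end: 70500000
    label: KIT
    copies_added: 1
Cs6:
  - chrom: "6"
    start: 70000000
    end: 70500000
    label: KIT
    copies_added: 1
  - chrom: "29"
    start: 20000000
    end: 20500000
    label: Cs6_chr29
    copies_added: 1
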
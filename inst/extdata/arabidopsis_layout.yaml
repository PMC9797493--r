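# Five nuclear Arabidopsis chromosomes (TAIR10 lengths) with approximate
# positions of the TT4/TT8 marker loci and one qPCR target inside each.
# Interval coordinates are 0-based half-open.
chromosomes:
  - {name: Chr1, length: 30427671}
  - {name: Chr2, length: 19698289}
  - {name: Chr3, length: 23459830}
  - {name: Chr4, length: 18585056}
  - {name: Chr5, length: 26975502}
loci:
  - {name: TT8, chrom: Chr4, start: 6200000, end: 6204643}
  - {name: TT4, chrom: Chr5, start: 4480000, end: 4481789}
amplicon_targets:
  - {name: TT8_q, chrom: Chr4, start: 6202000, end: 6202120}
  - {name: TT4_q, chrom: Chr5, start: 4480500, end: 4480620}
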
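# Demo run: a small two-subclone population with the same structure as the
# package defaults, sized so the full pipeline finishes in well under a minute.
seed: 7
annotation:
  n_chrom: 6
  chrom_size: 40000000
  bin_size: 10000000
  frags_per_bin: 400
  genes_per_bin: 10
simulation:
  subpops:
    I:
      n_cells: 4
      events:
        - {chrom: chr1, start: 0, end: 40000000, copy: 3}
        - {chrom: chr2, start: 0, end: 40000000, copy: 3}
        - {chrom: chr4, start: 0, end: 40000000, copy: 3}
        - {chrom: chr5, start: 0, end: 40000000, copy: 1}
    II:
      n_cells: 6
      events:
        - {chrom: chr1, start: 0, end: 40000000, copy: 3}
        - {chrom: chr3, start: 0, end: 40000000, copy: 1}
        - {chrom: chr6, start: 0, end: 40000000, copy: 1}
top_n: 100
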
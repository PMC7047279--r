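name: mic-ex2-ex5
amplicons:
- name: ex2
  segments:
  - exon: 2
    start: 0
- name: ex3
  segments:
  - exon: 3
    start: 0
- name: ex4-5
  segments:
  - exon: 4
    start: 65
  - exon: 5
    start: 0
    trim_end: 13
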
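# Named miRNA:target regions used throughout the analyses.
# track: L = miRNA (5'->3'), LT = target site (3'->5'); 1-based start.
seed2-6:
  track: L
  start: 2
  len: 6
L4-4:
  track: L
  start: 4
  len: 4
L13-4:
  track: L
  start: 13
  len: 4
L10-4:
  track: L
  start: 10
  len: 4
LT7-5:
  track: LT
  start: 7
  len: 5
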
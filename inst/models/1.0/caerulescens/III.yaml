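name: III
type: Migrations and divergence
status: inferred
topology: ((A,B),C)
ne:
  A: Ne_A
  B: Ne_B
  C: Ne_C
  AB: tied
  ABC: tied
params:
  Ne_A:
    lower: 10000.0
    upper: 2000000.0
  Ne_B:
    lower: 10000.0
    upper: 2000000.0
  Ne_C:
    lower: 10000.0
    upper: 2000000.0
  tdiv_AB:
    lower: 10000.0
    upper: 2580000.0
  tdiv_ABC:
    lower: 10000.0
    upper: 2580000.0
  tmig_A_B:
    lower: 1000.0
    upper: 2580000.0
  p_A_B:
    lower: 1.0e-05
    upper: 0.6
  tmig_B_A:
    lower: 1000.0
    upper: 2580000.0
  p_B_A:
    lower: 1.0e-05
    upper: 0.6
events:
- kind: split
  time: tdiv_AB
  child: A
  parent: AB
- kind: split
  time: tdiv_AB
  child: B
  parent: AB
- kind: split
  time: tdiv_ABC
  child: AB
  parent: ABC
- kind: split
  time: tdiv_ABC
  child: C
  parent: ABC
- kind: pulse
  time: tmig_A_B
  source: A
  dest: B
  fraction: p_A_B
- kind: pulse
  time: tmig_B_A
  source: B
  dest: A
  fraction: p_B_A
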
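name: I
type: Divergences
status: inferred
topology: ((A,B),C)
ne:
  A: Ne_A
  B: Ne_B
  C: Ne_C
  AB: Ne_AB
  ABC: Ne_ABC
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
  Ne_AB:
    lower: 10000.0
    upper: 2000000.0
  Ne_ABC:
    lower: 10000.0
    upper: 2000000.0
  tdiv_AB:
    lower: 10000.0
    upper: 10000000.0
  tdiv_ABC:
    lower: 10000.0
    upper: 10000000.0
  Ne_ANC:
    lower: 10000.0
    upper: 2000000.0
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
- kind: size_change
  time: 5000000.0
  pop: ABC
  new_ne: Ne_ANC
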
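# Circle_4 with closed 1-neighborhoods, nor vertex functions, sequential
# update in permutation (1,2,3,4). Enumerates all 16 states: one 7-cycle,
# maximum transient 1.
graph:
  template:
    name: circle
    n: 4
    self_loops: true
r: 2
functions:
  default:
    family: nor
scheme:
  sequential: [1, 2, 3, 4]
analyses: [phase_space, attractors, basins]
seed: 1
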
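# Small press test: drive the centre of the cube's top face downward at a
# constant velocity and record the reaction force at the driven node.
# Units: mm, g, s (forces in g mm/s^2).
geometry:
  kind: cube
  edge: 20
  divisions: 2
material:
  k1: 0.25
  k2: 10
  b0: 2
  b1: 1000
  alpha: 0
  dl_c_frac: 0.1
  k_ratio: 0.5
model:
  preset: entity
  mode: integrated
  overstretch: true
solver:
  dt: 0.01
  iterations: 5
  gravity: [0, 0, 0]
boundary_conditions:
  - kind: fixed
    nodes: bottom_face
  - kind: velocity
    nodes: top_center
    value: [0, 0, -4]
    t0: 0
    t1: 1
probe: top_center
duration: 1
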
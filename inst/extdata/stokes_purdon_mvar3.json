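{
  "comment": "Three-node MVAR(3) demonstration network (Stokes & Purdon's conditional-causality example, transcribed from the original work). Nodes resonate at 40, 10 and 50 Hz at Fs = 120 Hz (pole radii 0.9, 0.7, 0.8); node 1 drives node 2 (lag 2) and node 2 drives node 3 (lag 3). Innovation covariance identity.",
  "M": 3,
  "p": 3,
  "fs": 120,
  "expected_resonances_hz": [40, 10, 50],
  "A": [
    [[-0.9, 0, 0],
     [0, 1.2124355652982142, 0],
     [0, 0, -1.3856406460551018]],
    [[-0.81, 0, 0],
     [-0.356, -0.49, 0],
     [0, 0, -0.64]],
    [[0, 0, 0],
     [0, 0, 0],
     [0, -0.3098, 0]]
  ],
  "Sigma": [[1, 0, 0], [0, 1, 0], [0, 0, 1]]
}
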
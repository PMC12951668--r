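{
  "atoms": [
    {"element": "C", "sp3": true, "chiral": false},
    {"element": "C", "sp3": true, "chiral": false},
    {"element": "C", "sp3": true, "chiral": false},
    {"element": "C", "sp3": true, "chiral": false},
    {"element": "C", "sp3": true, "chiral": false},
    {"element": "C", "sp3": true, "chiral": false},
    {"element": "C", "sp3": true, "chiral": false},
    {"element": "C", "sp3": true, "chiral": false},
    {"element": "C", "sp3": true, "chiral": false},
    {"element": "C", "sp3": true, "chiral": false}
  ],
  "bonds": [[1,2],[2,3],[3,4],[4,5],[5,6],[6,7],[7,8],[8,9],[9,10]]
}
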
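class: Cryptomonas
provenance: 50
diameterABD 8.22 12.72

class: Micractinium
provenance: 50
diameterABD 15.85 40.52
intensity 73.64 105.85

class: Microcystis novacekii
provenance: 50
diameterABD 33.48 83.89
intensity 40.55 97.59
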
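class: Cryptomonas
provenance: intersection
diameterABD 8.23 11.53

class: Micractinium
provenance: intersection
diameterABD 16.19 40.52
intensity 79.20 105.85

class: Microcystis novacekii
provenance: intersection
diameterABD 45.35 83.89
intensity 49.12 92.47
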
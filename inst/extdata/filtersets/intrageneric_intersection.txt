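class: Microcystis aeruginosa
provenance: intersection
averageBlue 76.28 97.85
edgeGradient 99.93 159.87
perimeter 391.00 1460.73
ratioRedBlue 1.15 1.28
sigmaIntensity 23.72 34.09

class: Microcystis ichthyoblabe
provenance: intersection
averageBlue 77.64 96.30
intensity 83.81 110.43
length 60.17 128.39
ratioRedBlue 1.17 1.32
roughness 1.42 4.16
sigmaIntensity 22.14 28.37

class: Microcystis novacekii
provenance: intersection
intensity 48.36 74.81

class: Microcystis smithii
provenance: intersection
intensity 94.55 117.32
ratioRedGreen 1.17 1.35
roughness 2.19 10.70

class: Microcystis wesenbergii
provenance: intersection
averageBlue 65.24 85.13
intensity 73.59 98.04
ratioRedBlue 1.19 1.36
ratioRedGreen 1.17 1.23
sigmaIntensity 26.89 43.70
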
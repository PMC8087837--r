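class: Microcystis aeruginosa
provenance: 50
averageBlue 76.08 97.85
edgeGradient 96.11 159.87
perimeter 391.00 1460.73
ratioRedBlue 1.15 1.30
sigmaIntensity 23.68 35.70

class: Microcystis ichthyoblabe
provenance: 50
averageBlue 77.64 96.30
intensity 83.81 110.43
length 60.17 128.39
ratioRedBlue 1.15 1.32
roughness 1.38 4.16
sigmaIntensity 21.58 30.97

class: Microcystis novacekii
provenance: 50
intensity 46.45 74.81

class: Microcystis smithii
provenance: 50
intensity 93.98 120.00
ratioRedGreen 1.16 1.39
roughness 1.58 10.70

class: Microcystis wesenbergii
provenance: 50
averageBlue 61.31 85.13
intensity 67.25 98.04
ratioRedBlue 1.19 1.39
ratioRedGreen 1.15 1.27
sigmaIntensity 26.10 47.12
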
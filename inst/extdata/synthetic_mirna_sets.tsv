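region	feature_id
hippocampus	miR-128-3p
hippocampus	miR-HI-01
hippocampus	miR-HI-02
hippocampus	miR-HI-03
hippocampus	miR-HI-04
hippocampus	miR-HI-05
hippocampus	miR-HI-06
hippocampus	miR-HI-07
olfactory_bulb	miR-128-3p
olfactory_bulb	let-7i-5p
olfactory_bulb	miR-OL-01
olfactory_bulb	miR-OL-02
olfactory_bulb	miR-OL-03
olfactory_bulb	miR-OL-04
olfactory_bulb	miR-OL-05
neocortex	let-7i-5p
neocortex	miR-NE-01
neocortex	miR-NE-02
neocortex	miR-NE-03
neocortex	miR-NE-04
neocortex	miR-NE-05
neocortex	miR-NE-06
neocortex	miR-NE-07
neocortex	miR-NE-08
neocortex	miR-NE-09
neocortex	miR-NE-10
brainstem	miR-BR-01
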
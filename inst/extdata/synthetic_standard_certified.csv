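# SYNTHETIC calibration-standard certificate for simulation and testing.
# Mass fractions loosely modeled on a dried biological reference material
# (liver-tissue scale); NOT a certificate of any real reference material.
element,certified_ppm
Ca,116
Fe,184
Cu,160
Zn,127
Sr,136

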
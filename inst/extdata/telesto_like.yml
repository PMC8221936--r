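# Reference optical configuration: 1.3-um spectral-domain OCT system with
# an f = 36 mm scan lens (aperture radius 3.5 mm), 1024 spectral samples.
# All values SI. Keys mirror oct_system() arguments; omitted keys take the
# package defaults.
f2: 36.0e-3
Ra: 3.5e-3
lambda0: 1.3e-6
bandwidth: 170.0e-9
n_k: 1024
nb: 1.0
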
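# Example model configuration: one [section] per model, key = value pairs.
# `model` names the built-in family; every other key is a numeric parameter.

[toy-subcritical]
model = toy
alpha = 0.4

[pdpc-monostable]
model = pdpc
v2 = 1.82

[pdpc-bistable]
model = pdpc
v2 = 3.04
k1 = 0.1
k2 = 1
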
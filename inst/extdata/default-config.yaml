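# Default model configuration. An empty mapping: every parameter takes
# the packaged published default (see ?model_parameters). Override any
# field by adding `name: value` lines, e.g.
#   dt: 0.25
#   sigma_noise: 0.01
{}
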
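# Conduction-velocity run for the AOE2 scenario (channels fixed in place,
# passive n1/j1 inserts), finer time step than the default.
protocol: cv
condition: AOE2
dt: 0.0005
stimulus:
  amplitude: 0.2
  duration: 0.2
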
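# Example configuration: constant CCW torque (push mode), desk-scale
# resolution.  All omitted keys take the package defaults; units g-um-s.
motor:
  tau: 0.002
  duration: 0.04
output:
  record_every: 2000
  snap_every: 2
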
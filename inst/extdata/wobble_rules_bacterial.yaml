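# Default bacterial wobble rule set: third-position pairs allowed beyond
# Watson-Crick, with efficiency weights relative to a WC pair (1.0).
# Anticodon-34 A is treated as inosine (pairs C3, A3, U3).
wobble_efficiency: 0.64
inosine_a34: true
cau_as_ile: false
strict_anticodons: true
pairs:
  - {ac34: G, c3: U, weight: 0.64}
  - {ac34: U, c3: G, weight: 0.64}
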
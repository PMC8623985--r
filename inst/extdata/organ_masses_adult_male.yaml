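# Reference adult-male organ masses (grams) for mouse-to-human extrapolation
# and local-deposition S-value generation.
provenance: >
  Adult male mathematical phantom reference masses of the Cristy-Eckerman
  (ORNL) series, the anatomy underlying classic internal-dosimetry codes for
  a ~73 kg adult. Paired organs (kidneys, lungs) are the combined mass;
  'large intestine' is the upper + lower large intestine wall; 'bone' is the
  mineral skeleton excluding marrow; 'blood' is total blood mass, used only
  to size the total-body remainder source; 'total body' is the reference
  whole-body mass.
adrenals: 16.3
blood: 5300
bone: 5000
bone marrow: 1120
brain: 1420
heart: 316
kidney: 299
large intestine: 387
liver: 1910
lung: 1000
muscle: 28000
pancreas: 94.3
small intestine: 677
spleen: 183
stomach: 158
thyroid: 20.7
total body: 73000
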
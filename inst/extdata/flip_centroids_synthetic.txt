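# Synthetic peptide-flip cluster centroid geometries (reference-frame
# coordinates, Angstrom). Constructed from an ideal trans peptide to
# satisfy the published rotation classes (~180, ~180, +120, -120 degrees)
# and flanking-CA translations > 0.2 A; these are synthetic stand-ins for
# the empirically clustered centroids.
cluster reference 0
CA1 0.000000 0.000000 0.000000
C1 1.428421 0.534077 -0.000000
O1 1.648518 1.745241 -0.000000
N2 2.395638 -0.377369 -0.000000
CA2 3.803955 -0.000000 -0.000000
cluster tweaked_down 178
CA1 0.150000 -0.900000 0.000000
C1 1.674808 -0.884520 0.018639
O1 2.315359 -1.934886 0.060908
N2 2.204212 0.295607 -0.013170
CA2 3.653955 0.450000 -0.000000
cluster simple_down 180
CA1 0.000000 -0.280000 0.000000
C1 1.490976 -0.600339 -0.000000
O1 1.885126 -1.766532 0.000000
N2 2.355693 0.448230 -0.000000
CA2 3.803955 0.280000 -0.000000
cluster left 120
CA1 0.000000 -0.250000 0.000000
C1 1.451040 -0.328608 0.462524
O1 1.748180 -0.900342 1.511423
N2 2.383059 0.253542 -0.326811
CA2 3.803955 0.250000 -0.000000
cluster right -120
CA1 0.000000 -0.250000 0.000000
C1 1.451040 -0.328608 -0.462524
O1 1.748180 -0.900342 -1.511423
N2 2.383059 0.253542 0.326811
CA2 3.803955 0.250000 -0.000000
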
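synthetic ff14SB-style coverage tuples for the CSG residue (placeholder constants, bookkeeping only)
BOND
N -H   300.0   1.500
N -CX  300.0   1.500
CX-H1  300.0   1.500
CX-2C  300.0   1.500
CX-C   300.0   1.500
C -O   300.0   1.500
2C-H1  300.0   1.500
2C-S   300.0   1.500
S -S   300.0   1.500
S -2C  300.0   1.500
2C-CX  300.0   1.500
CX-N   300.0   1.500
C -N   300.0   1.500
N -C   300.0   1.500
C -2C  300.0   1.500
2C-HC  300.0   1.500
2C-2C  300.0   1.500
CX-HP  300.0   1.500
CX-N3  300.0   1.500
CX-CO  300.0   1.500
N3-H   300.0   1.500
CO-O2  300.0   1.500

ANGLE
H -N -CX   50.0  109.50
N -CX-H1   50.0  109.50
N -CX-2C   50.0  109.50
N -CX-C    50.0  109.50
H1-CX-2C   50.0  109.50
H1-CX-C    50.0  109.50
2C-CX-C    50.0  109.50
CX-2C-H1   50.0  109.50
CX-2C-S    50.0  109.50
H1-2C-H1   50.0  109.50
H1-2C-S    50.0  109.50
CX-C -O    50.0  109.50
2C-S -S    50.0  109.50
S -S -2C   50.0  109.50
S -2C-H1   50.0  109.50
S -2C-CX   50.0  109.50
H1-2C-CX   50.0  109.50
2C-CX-H1   50.0  109.50
2C-CX-N    50.0  109.50
H1-CX-N    50.0  109.50
CX-N -H    50.0  109.50
CX-N -C    50.0  109.50
H -N -C    50.0  109.50
CX-C -N    50.0  109.50
O -C -N    50.0  109.50
C -N -H    50.0  109.50
C -N -CX   50.0  109.50
N -C -O    50.0  109.50
N -C -2C   50.0  109.50
O -C -2C   50.0  109.50
C -2C-HC   50.0  109.50
C -2C-2C   50.0  109.50
HC-2C-HC   50.0  109.50
HC-2C-2C   50.0  109.50
2C-2C-HC   50.0  109.50
2C-2C-CX   50.0  109.50
HC-2C-CX   50.0  109.50
2C-CX-HP   50.0  109.50
2C-CX-N3   50.0  109.50
2C-CX-CO   50.0  109.50
HP-CX-N3   50.0  109.50
HP-CX-CO   50.0  109.50
N3-CX-CO   50.0  109.50
CX-N3-H    50.0  109.50
H -N3-H    50.0  109.50
CX-CO-O2   50.0  109.50
O2-CO-O2   50.0  109.50
N -CX-CO   50.0  109.50
H1-CX-H1   50.0  109.50
H1-CX-CO   50.0  109.50

DIHE
X -N -CX-X    1    0.000       0.000           2.000
X -CX-2C-X    1    0.000       0.000           2.000
X -CX-C -X    1    0.000       0.000           2.000
X -2C-S -X    1    0.000       0.000           2.000
X -S -S -X    1    0.000       0.000           2.000
X -S -2C-X    1    0.000       0.000           2.000
X -2C-CX-X    1    0.000       0.000           2.000
X -CX-N -X    1    0.000       0.000           2.000
X -C -N -X    1    0.000       0.000           2.000
X -N -C -X    1    0.000       0.000           2.000
X -C -2C-X    1    0.000       0.000           2.000
X -2C-2C-X    1    0.000       0.000           2.000
X -CX-N3-X    1    0.000       0.000           2.000
X -CX-CO-X    1    0.000       0.000           2.000

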
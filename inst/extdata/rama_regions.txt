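# Ramachandran region map: seven regions as rectangular (phi,psi) boxes.
# One box per line: index label phi_min phi_max psi_min psi_max
# A point belongs to the first box in file order that contains it
# (half-open [min,max); max=180 inclusive). Region 7 is the catch-all,
# so the map is total on the torus.
1 core-helical        -100  -30  -80   -5
2 broad-helical       -180    0 -120   45
3 core-strand         -180 -105  120  180
3 core-strand         -180 -105 -180 -155
4 broad-strand        -180 -105   45  180
4 broad-strand        -180 -105 -180 -120
5 polyproline-II      -105  -30   45  180
6 left-handed-helical    0  180  -45   90
7 other               -180  180 -180  180
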
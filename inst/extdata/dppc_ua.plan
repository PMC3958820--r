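# DPPC united-atom move plan: 18 breakage x3 + 22 crankshaft + 8 torsion + 4 bond_angle = 88 DOF
# breakage atoms (Cartesian moves with chain closure of bonded neighbors)
breakage 3 0.05
breakage 6 0.05
breakage 8 0.05
breakage 10 0.05
breakage 15 0.05
breakage 17 0.05
breakage 19 0.05
breakage 21 0.05
breakage 23 0.05
breakage 25 0.05
breakage 12 0.05
breakage 29 0.05
breakage 31 0.05
breakage 33 0.05
breakage 35 0.05
breakage 37 0.05
breakage 39 0.05
breakage 41 0.05
# crankshaft rotations of closure atoms about their flanking-atom axes
crankshaft 2 30
crankshaft 4 30
crankshaft 5 30
crankshaft 7 30
crankshaft 9 30
crankshaft 11 30
crankshaft 14 30
crankshaft 16 30
crankshaft 18 30
crankshaft 20 30
crankshaft 22 30
crankshaft 24 30
crankshaft 26 30
crankshaft 27 30
crankshaft 13 30
crankshaft 30 30
crankshaft 32 30
crankshaft 34 30
crankshaft 36 30
crankshaft 38 30
crankshaft 40 30
crankshaft 42 30
# internal-coordinate moves of terminal moieties and external groups
torsion 3 2 30        # choline head (N + methyls) about bond 2-3
torsion 2 1 30        # N-methyl trio about bond 1-2
torsion 4 5 30 47     # phosphate oxygen 47 about bond 4-5
torsion 9 10 20 49    # sn-2 carbonyl oxygen about the ester bond
torsion 12 13 20 50   # sn-1 carbonyl oxygen about the ester bond
torsion 25 26 30      # sn-2 chain end (atoms 27, 28)
torsion 26 27 30      # sn-2 terminal methyl
torsion 41 42 30      # sn-1 terminal methyl
bond_angle 3 2 1 8
bond_angle 25 26 27 8
bond_angle 26 27 28 8
bond_angle 41 42 43 8
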
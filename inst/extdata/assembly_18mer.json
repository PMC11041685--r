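{"format":"hexfract-assembly","version":1,"level":1,"params":{"hexamer_width":10,"monomer_radius":2.2,"ring_radius":3.33333333333333,"dihedral_level1":60,"dihedral_level2":34,"planar":true},"provenance":{"generator":"build_sierpinski","args":{"level":1},"seed":null},"hexamers":[{"id":0,"dimer1":0,"dimer2":1,"dimer3":2,"x":3.53525079574969e-16,"y":5.77350269189626,"z":0,"orientation":90},{"id":1,"dimer1":3,"dimer2":4,"dimer3":5,"x":-5,"y":-2.88675134594813,"z":0,"orientation":90},{"id":2,"dimer1":6,"dimer2":7,"dimer3":8,"x":5,"y":-2.88675134594813,"z":0,"orientation":90}],"dimers":[{"id":0,"monomer1":0,"monomer2":1,"hexamer_id":0,"corner_dx":6.12323399573677e-17,"corner_dy":1,"slot":"open"},{"id":1,"monomer1":2,"monomer2":3,"hexamer_id":0,"corner_dx":-0.866025403784439,"corner_dy":-0.5,"slot":"bonded"},{"id":2,"monomer1":4,"monomer2":5,"hexamer_id":0,"corner_dx":0.866025403784438,"corner_dy":-0.5,"slot":"bonded"},{"id":3,"monomer1":6,"monomer2":7,"hexamer_id":1,"corner_dx":6.12323399573677e-17,"corner_dy":1,"slot":"bonded"},{"id":4,"monomer1":8,"monomer2":9,"hexamer_id":1,"corner_dx":-0.866025403784439,"corner_dy":-0.5,"slot":"open"},{"id":5,"monomer1":10,"monomer2":11,"hexamer_id":1,"corner_dx":0.866025403784438,"corner_dy":-0.5,"slot":"bonded"},{"id":6,"monomer1":12,"monomer2":13,"hexamer_id":2,"corner_dx":6.12323399573677e-17,"corner_dy":1,"slot":"bonded"},{"id":7,"monomer1":14,"monomer2":15,"hexamer_id":2,"corner_dx":-0.866025403784439,"corner_dy":-0.5,"slot":"bonded"},{"id":8,"monomer1":16,"monomer2":17,"hexamer_id":2,"corner_dx":0.866025403784438,"corner_dy":-0.5,"slot":"open"}],"monomers":[{"id":0,"dimer_id":0,"hexamer_id":0,"x":1.66666666666667,"y":8.66025403784439,"z":0,"participates":false},{"id":1,"dimer_id":0,"hexamer_id":0,"x":-1.66666666666667,"y":8.66025403784439,"z":0,"participates":false},{"id":2,"dimer_id":1,"hexamer_id":0,"x":-3.33333333333333,"y":5.77350269189626,"z":0,"participates":false},{"id":3,"dimer_id":1,"hexamer_id":0,"x":-1.66666666666667,"y":2.88675134594813,"z":0,"participates":true},{"id":4,"dimer_id":2,"hexamer_id":0,"x":1.66666666666667,"y":2.88675134594813,"z":0,"participates":true},{"id":5,"dimer_id":2,"hexamer_id":0,"x":3.33333333333333,"y":5.77350269189626,"z":0,"participates":false},{"id":6,"dimer_id":3,"hexamer_id":1,"x":-3.33333333333333,"y":-8.88178419700125e-16,"z":0,"participates":true},{"id":7,"dimer_id":3,"hexamer_id":1,"x":-6.66666666666667,"y":-4.44089209850063e-16,"z":0,"participates":false},{"id":8,"dimer_id":4,"hexamer_id":1,"x":-8.33333333333333,"y":-2.88675134594813,"z":0,"participates":false},{"id":9,"dimer_id":4,"hexamer_id":1,"x":-6.66666666666667,"y":-5.77350269189626,"z":0,"participates":false},{"id":10,"dimer_id":5,"hexamer_id":1,"x":-3.33333333333333,"y":-5.77350269189626,"z":0,"participates":false},{"id":11,"dimer_id":5,"hexamer_id":1,"x":-1.66666666666667,"y":-2.88675134594813,"z":0,"participates":true},{"id":12,"dimer_id":6,"hexamer_id":2,"x":6.66666666666667,"y":-3.10862446895044e-15,"z":0,"participates":false},{"id":13,"dimer_id":6,"hexamer_id":2,"x":3.33333333333333,"y":-2.66453525910038e-15,"z":0,"participates":true},{"id":14,"dimer_id":7,"hexamer_id":2,"x":1.66666666666667,"y":-2.88675134594813,"z":0,"participates":true},{"id":15,"dimer_id":7,"hexamer_id":2,"x":3.33333333333333,"y":-5.77350269189626,"z":0,"participates":false},{"id":16,"dimer_id":8,"hexamer_id":2,"x":6.66666666666667,"y":-5.77350269189626,"z":0,"participates":false},{"id":17,"dimer_id":8,"hexamer_id":2,"x":8.33333333333333,"y":-2.88675134594813,"z":0,"participates":false}],"fractal_bonds":[{"dimer1":1,"dimer2":3},{"dimer1":2,"dimer2":6},{"dimer1":5,"dimer2":7}]}
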
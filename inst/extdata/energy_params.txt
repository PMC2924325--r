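# riboSnitch simplified nearest-neighbour energy parameter set
# schema (whitespace-separated key-value lines, '#' comments):
#   param_set_version <string>
#   temperature <kelvin>
#   gas_constant <kcal/(mol*K)>
#   min_hairpin_loop <int>            minimum unpaired bases in a hairpin loop
#   max_interior_unpaired <int>       cap on total unpaired bases in bulge/interior loops
#   loop_extrapolation_coeff <real>   E(l) = E(Lmax) + coeff * R*T * ln(l/Lmax) beyond tables
#   multiloop_offset|branch|unpaired <kcal/mol>  linear multiloop model
#   allowed_pairs <pair> ...          unordered residue pairs that may form
#   stack <outer> <inner> <kcal/mol>  outer pair (i,j) stacked on inner pair (i+1,j-1)
#   hairpin|bulge|internal <loop length> <kcal/mol>
param_set_version 1.0
temperature 310.15
gas_constant 0.0019872
min_hairpin_loop 3
max_interior_unpaired 30
loop_extrapolation_coeff 1.75
multiloop_offset 3.4
multiloop_branch 0.4
multiloop_unpaired 0.0
allowed_pairs AU UA GC CG GU UG
stack AU AU -0.9
stack AU CG -2.2
stack AU GC -2.1
stack AU GU -0.6
stack AU UA -1.1
stack AU UG -1.4
stack CG AU -2.1
stack CG CG -3.3
stack CG GC -2.4
stack CG GU -1.4
stack CG UA -2.1
stack CG UG -2.1
stack GC AU -2.4
stack GC CG -3.4
stack GC GC -3.3
stack GC GU -1.5
stack GC UA -2.2
stack GC UG -2.5
stack GU AU -1.3
stack GU CG -2.5
stack GU GC -2.1
stack GU GU -0.5
stack GU UA -1.4
stack GU UG 1.3
stack UA AU -1.3
stack UA CG -2.4
stack UA GC -2.1
stack UA GU -1.0
stack UA UA -0.9
stack UA UG -1.3
stack UG AU -1.0
stack UG CG -1.5
stack UG GC -1.4
stack UG GU 0.3
stack UG UA -0.6
stack UG UG -0.5
hairpin 3 5.4
hairpin 4 5.6
hairpin 5 5.7
hairpin 6 5.4
hairpin 7 6.0
hairpin 8 5.5
hairpin 9 6.4
hairpin 10 6.5
bulge 1 3.9
bulge 2 3.1
bulge 3 3.5
bulge 4 4.2
bulge 5 4.8
bulge 6 5.0
bulge 7 5.2
bulge 8 5.3
bulge 9 5.4
bulge 10 5.5
internal 2 4.1
internal 3 5.1
internal 4 4.9
internal 5 5.3
internal 6 5.7
internal 7 5.9
internal 8 6.0
internal 9 6.1
internal 10 6.3
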
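"age_lo","age_hi","weight"
18,18,0.0246228088025815
19,19,0.0246228088025815
20,24,0.119480217448182
25,29,0.1152649786331
30,34,0.110613680630251
35,39,0.103927439751156
40,44,0.0957876682461699
45,49,0.0877932498037734
50,54,0.0780545946103084
55,59,0.0661356434780081
60,64,0.0540713392831187
65,69,0.0430245065263525
70,74,0.0321230268321754
75,79,0.0220936655135324
80,Inf,0.0223843716387104
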
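frame,g16_pl,g16_p,g16_l,g16_de,ani_pl,ani_p,ani_l,ani_de,abs_err
0,-601409.137,-543088.071,-58316.912,-4.154,-601407.549,-543086.919,-58316.653,-3.977,0.177
1,-611338.434,-553017.357,-58317.024,-4.053,-611337.259,-553016.927,-58316.904,-3.428,0.625
2,-611343.896,-553023.284,-58316.737,-3.876,-611342.856,-553022.874,-58316.543,-3.439,0.436
3,-611338.693,-553021.427,-58316.102,-1.164,-611337.181,-553020.251,-58315.918,-1.012,0.152
100,-611340.901,-553023.152,-58315.756,-1.992,-611340.670,-553023.116,-58315.703,-1.878,0.115
mean,-611366.228,-553047.220,-58316.584,-2.424,-611368.035,-553046.484,-58319.368,-2.183,0.252
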
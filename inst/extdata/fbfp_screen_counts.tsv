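library	beneficial	deleterious	neutral
F37X	2	71	103
D52X	0	42	138
A53X	0	60	57
R54X	0	28	152
Q57X	0	30	150
R70X	0	18	120
N85X	0	141	20
W94X	0	15	58
Y112X	0	31	149
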
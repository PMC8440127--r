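category	p_accessory_vs_generalist	p_accessory_vs_specialist	p_generalist_vs_specialist	bh_accessory_vs_generalist	bh_accessory_vs_specialist	bh_generalist_vs_specialist
J	0.326101	0.114384	0.32189	FALSE	FALSE	FALSE
A	0.770197	0.86256	ND	FALSE	FALSE	FALSE
K	0.660644	0.001324	0.005024	FALSE	TRUE	FALSE
L	0.016087	0.454098	0.458151	FALSE	FALSE	FALSE
B	ND	ND	ND	FALSE	FALSE	FALSE
D	0.233915	0.902782	0.498252	FALSE	FALSE	FALSE
Y	ND	ND	ND	FALSE	FALSE	FALSE
V	0.253986	0.908512	0.590247	FALSE	FALSE	FALSE
T	0.546536	0.086224	0.073969	FALSE	FALSE	FALSE
M	0.609181	0.285109	0.484595	FALSE	FALSE	FALSE
N	0.330625	0.666394	0.873454	FALSE	FALSE	FALSE
Z	ND	ND	ND	FALSE	FALSE	FALSE
W	0.795567	0.973348	0.906121	FALSE	FALSE	FALSE
U	0.164648	0.519524	0.133258	FALSE	FALSE	FALSE
O	0.74121	0.073661	0.129009	FALSE	FALSE	FALSE
X	0.003727	0.155424	0.688248	FALSE	FALSE	FALSE
C	0.115125	0.690668	0.197208	FALSE	FALSE	FALSE
G	0.971753	0.014538	0.025503	FALSE	FALSE	FALSE
E	0.000799	0.679508	0.012048	TRUE	FALSE	FALSE
F	0.062515	0.913128	0.279673	FALSE	FALSE	FALSE
H	0.002552	0.136954	0.679383	TRUE	FALSE	FALSE
I	0.018139	0.633887	0.046447	FALSE	FALSE	FALSE
P	0.275201	0.034176	0.140896	FALSE	FALSE	FALSE
Q	0.159491	0.383424	0.094268	FALSE	FALSE	FALSE
R	0.149804	0.147752	0.581598	FALSE	FALSE	FALSE
S	0.145587	0.624075	0.713207	FALSE	FALSE	FALSE
Not_assigned	0	0	0.804117	TRUE	TRUE	FALSE
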
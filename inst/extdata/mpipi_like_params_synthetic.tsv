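residue	mass	charge	sigma	eps	mu	nu
A	71.08	0	5.04	0.16	1	1
R	156.19	1	6.56	0.30	1	1
N	114.10	0	5.68	0.18	1	1
D	115.09	-1	5.58	0.13	1	1
C	103.14	0	5.48	0.26	1	1
Q	128.13	0	6.02	0.18	1	1
E	129.12	-1	5.92	0.13	1	1
G	57.05	0	4.50	0.13	1	1
H	137.14	0	6.08	0.25	1	1
I	113.16	0	6.18	0.28	1	1
L	113.16	0	6.18	0.28	1	1
K	128.17	1	6.36	0.14	1	1
M	131.19	0	6.18	0.30	1	1
F	147.18	0	6.36	0.38	1	1
P	97.12	0	5.56	0.22	1	1
S	87.08	0	5.18	0.14	1	1
T	101.10	0	5.62	0.16	1	1
V	99.07	0	5.86	0.26	1	1
W	186.21	0	6.78	0.46	1	1
Y	163.18	0	6.46	0.42	1	1
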
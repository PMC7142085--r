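# Residue property scales used by builtin_scales(). Edit or extend freely:
# each column after 'aa' is one scale; all 20 standard residues must be present.
# order_propensity is derived in code as -disorder_propensity.
aa	aromaticity	polarity	charge	hydrophobicity	flexibility	exposure	beta_frequency	coil_frequency	disorder_propensity	bulkiness
A	0	0.00	0	1.8	0.357	-0.3	0.83	0.66	0.060	11.50
R	0	52.00	1	-4.5	0.529	1.4	0.93	0.95	0.180	14.28
N	0	3.38	0	-3.5	0.463	0.5	0.89	1.56	0.007	12.82
D	0	49.70	-1	-3.5	0.511	0.6	0.54	1.46	0.192	11.68
C	0	1.48	0	2.5	0.346	-0.9	1.19	1.19	-0.020	13.46
Q	0	3.53	0	-3.5	0.493	0.7	1.10	0.98	0.318	14.45
E	0	49.90	-1	-3.5	0.497	0.7	0.37	0.74	0.736	13.57
G	0	0.00	0	-0.4	0.544	-0.3	0.75	1.56	0.166	3.40
H	1	51.60	0	-3.2	0.323	0.1	0.87	0.95	0.303	13.69
I	0	0.13	0	4.5	0.462	-0.7	1.60	0.47	-0.486	21.40
L	0	0.13	0	3.8	0.365	-0.5	1.30	0.59	-0.326	21.40
K	0	49.50	1	-3.9	0.466	1.8	0.74	1.01	0.586	15.71
M	0	1.43	0	1.9	0.295	-0.4	1.05	0.60	-0.397	16.25
F	1	0.35	0	2.8	0.314	-0.5	1.38	0.60	-0.697	19.80
P	0	1.58	0	-1.6	0.509	0.3	0.55	1.52	0.987	17.43
S	0	1.67	0	-0.8	0.507	0.1	0.75	1.43	0.341	9.47
T	0	1.66	0	-0.7	0.444	0.2	1.19	0.96	0.059	15.77
W	1	2.10	0	-0.9	0.305	-0.3	1.37	0.96	-0.884	21.67
Y	1	1.61	0	-1.3	0.420	0.4	1.47	1.14	-0.510	18.03
V	0	0.13	0	4.2	0.386	-0.6	1.70	0.50	-0.121	21.57
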
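# random-coil reference chemical shifts (ppm), Wishart-style compilation
# replaceable by the user; neighbour/temperature/pH corrections default to zero
residue	nucleus	shift_ppm
A	CA	52.5
R	CA	56.0
N	CA	53.1
D	CA	54.2
C	CA	58.2
Q	CA	55.7
E	CA	56.6
G	CA	45.1
H	CA	55.0
I	CA	61.1
L	CA	55.1
K	CA	56.2
M	CA	55.4
F	CA	57.7
P	CA	63.3
S	CA	58.3
T	CA	61.8
W	CA	57.5
Y	CA	57.9
V	CA	62.2
A	CB	19.1
R	CB	30.9
N	CB	38.9
D	CB	41.1
C	CB	28.0
Q	CB	29.4
E	CB	29.9
H	CB	29.0
I	CB	38.8
L	CB	42.4
K	CB	33.1
M	CB	32.9
F	CB	39.6
P	CB	32.1
S	CB	63.8
T	CB	69.8
W	CB	29.6
Y	CB	38.8
V	CB	32.9
A	CO	177.8
R	CO	176.3
N	CO	175.2
D	CO	176.3
C	CO	174.6
Q	CO	176.0
E	CO	176.6
G	CO	174.9
H	CO	174.1
I	CO	176.4
L	CO	177.6
K	CO	176.6
M	CO	176.3
F	CO	175.8
P	CO	177.3
S	CO	174.6
T	CO	174.7
W	CO	176.1
Y	CO	175.9
V	CO	176.3
A	HA	4.32
R	HA	4.34
N	HA	4.74
D	HA	4.64
C	HA	4.71
Q	HA	4.34
E	HA	4.35
G	HA	3.96
H	HA	4.73
I	HA	4.17
L	HA	4.34
K	HA	4.32
M	HA	4.48
F	HA	4.62
P	HA	4.42
S	HA	4.47
T	HA	4.35
W	HA	4.66
Y	HA	4.55
V	HA	4.12
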
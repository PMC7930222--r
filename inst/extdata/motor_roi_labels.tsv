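index	area	abbreviation	atlas
1	Left thalamus	ThalamusL	MNI structural
2	Right thalamus	ThalamusR	MNI structural
3	Left premotor cortex Brodmann area 6	PcBA6L	Juelich histological
4	Right premotor cortex Brodmann area 6	PcBA6R	Juelich histological
5	Left anterior primary motor cortex Brodmann area 4	PmcBA4aL	Juelich histological
6	Right anterior primary motor cortex Brodmann area 4	PmcBA4aR	Juelich histological
7	Left posterior primary motor cortex Brodmann area 4	PmcBA4pL	Juelich histological
8	Right posterior primary motor cortex Brodmann area 4	PmcBA4pR	Juelich histological
9	Left visual cortex V1 Brodmann area 17	V1BA17L	Juelich histological
10	Right visual cortex V1 Brodmann area 17	V1BA17R	Juelich histological
11	Left visual cortex V2 Brodmann area 18	V1BA18L	Juelich histological
12	Right visual cortex V2 Brodmann area 18	V1BA18R	Juelich histological
13	Cerebellum	Cereb	Harvard-Oxford cortical structural
14	Frontal lobe	FL	Harvard-Oxford cortical structural
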
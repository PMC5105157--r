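site	taxon	group	count
Qajaa	Monodon monoceros	cetacean	2
Qajaa	Cetacea indet.	cetacean	1
Qajaa	all excavated bones	total	15000
Qeqertasussuk	whale bone, teeth and baleen	cetacean	102
Qeqertasussuk	all excavated bones	total	100000
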
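name	nisp	mni	per_individual_mass_kg	expected_biomass_kg
Pagophilus groenlandicus	6000	170	130	254150
Pusa hispida	900	40	60	27600
Rangifer tarandus	800	25	100	28750
Vulpes lagopus	400	30	3.5	1207.5
Larus	1200	90	1.2	1242
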
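# Fossil calibration table used for the cetacean dating analysis (ages in Ma).
# min_type/max_type: hard = zero tail probability, soft = 2.5% tail.
node_label	t_min	min_type	t_max	max_type
Perissodactyla_Cetartiodactyla_root	52.40	hard	164.6	soft
Crown_Cetartiodactyla	52.40	hard	66.00	soft
Cetruminantia	52.40	hard	66.00	soft
Whippomorpha	52.40	hard	66.00	soft
Crown_Bovidae	16.00	hard	28.00	soft
Crown_Cetacea	36.40	hard	52.40	soft
Crown_Mysticeti	25.20	hard	36.40	soft
Crown_Ziphiidae	13.20	hard	23.00	soft
Phocoenidae_Monodontidae	7.50	hard	19.50	soft
Delphinidae_excl_L_albirostris	8.5	hard	19.50	soft
Delphininae_excl_S_guianensis	3.98	hard	8.5	soft
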
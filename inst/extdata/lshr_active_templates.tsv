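pdb_id	chain_id	sequence	rank_score	seq_identity	family	subfamily	gpcr_state	dfg	ac_helix	salt_bridge	a_loop	coords_path
6H7L	A	MKTIIALSYIFCLVFA	95.0	20.6	ClassA	Prostanoid	Active	unknown	unknown	unknown	unknown	NA
6IBL	A	MKTIIALSYIFCLVFA	90.0	15.9	ClassA	Melatonin	Active	unknown	unknown	unknown	unknown	NA
6K41	R	MKTIIALSYIFCLVFA	85.0	23.1	ClassA	Prostanoid	Active	unknown	unknown	unknown	unknown	NA
6K42	R	MKTIIALSYIFCLVFA	80.0	23.7	ClassA	Prostanoid	Active	unknown	unknown	unknown	unknown	NA
5X7D	A	MKTIIALSYIFCLVFA	75.0	28.4	ClassA	Glycoprotein hormone	Inactive	unknown	unknown	unknown	unknown	NA
4ZJ8	A	MKTIIALSYIFCLVFA	70.0	31.2	ClassA	Glycoprotein hormone	Inactive	unknown	unknown	unknown	unknown	NA
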
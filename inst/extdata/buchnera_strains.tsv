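# Genome metadata for the four Buchnera strains; cds_count values are
# consistent with the printed transporter-gene percentages (16/17/16/10 %).
strain	host	genome_kb	cds_count	membranes	pct_transporter_cds
BAp	Acyrthosiphon pisum	641	564	inner,outer	16
BSg	Schizaphis graminum	641	545	inner,outer	17
BBp	Baizongia pistaciae	616	507	inner	16
BCc	Cinara cedri	416	362	inner,outer	10
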
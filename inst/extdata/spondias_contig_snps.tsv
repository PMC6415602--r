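contig	length_bp	s_tuberosa	s_bahiensis	s_mombin	interspecific
Contig_A	54663	24	936	39	946
Contig_B	51123	6	892	0	621
Contig_C	49173	0	838	13	778
Contig_D	47249	1	828	18	676
Contig_E	50619	1	834	48	821
Contig_F	48859	31	678	30	835
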
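peptide	mean_stretch	sd_stretch	mean_relax	sd_relax	delta_g_reported
neck_linker	1569.9	24.9	1211.6	68.2	1462.4
ala_only	949.7	23.9	696.0	81.5	882
no_asparagine	733.7	30.5	651.0	63.3	690.5
no_lysine	985.6	40.4	388.0	66.7	752.8
no_proline	1056.8	26.8	888.0	63.9	997.6
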
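pipeline	n_calls	frames_thousands	runtime_s
integrate_multiframe	42575	1230	2.1
subtract_sas_analysis	11214	336	7.3
hplc_analysis	709	893	2.9
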
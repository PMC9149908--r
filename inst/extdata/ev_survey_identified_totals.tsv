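dataset	identified_proteins
misev2018	561
kowal_f3_100k	2979
kugeratski_core_exosome	1243
kugeratski_cell_exosome	6491
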
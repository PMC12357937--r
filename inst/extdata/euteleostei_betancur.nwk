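(tetrapod_outgroup,(basal_rayfinned,(elopomorpha_ostariophysi,((salmoniformes_esociformes_argentiniformes,galaxiiformes),(osmeriformes_stomiiformes,(eurypterygii_other,((straightnose_pipefish,seahorse_clade)Syngnathiformes,(basal_notothenioids,notothenioid_crown)Notothenioidei))Eurypterygii))Euteleostei)Teleostei)Actinopterygii)Gnathostomata;
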
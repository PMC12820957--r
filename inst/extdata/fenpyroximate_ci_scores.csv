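ligand_id,gold_chemplp_fitness,gold_chemscore_fitness,gold_goldscore_fitness,mmgbsa_dg_bind_gold,mbae_aset_gold,mbae_del_gold,glide_docking_score,glide_ifdscore,mmgbsa_dg_bind_glide,mbae_aset_glide,mbae_del_glide
E-FPM,86.32,28.77,62.01,-53.22,-251.30,-162.35,-9.14,-3173.87,-56.31,-241.70,-203.43
Z-FPM,80.59,27.47,51.33,-40.61,-244.66,-168.63,-8.70,-3170.89,-34.79,-235.88,-206.22
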
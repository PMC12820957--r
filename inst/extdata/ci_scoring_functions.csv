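name,program,direction
gold_chemplp_fitness,GOLD,higher_is_better
gold_chemscore_fitness,GOLD,higher_is_better
gold_goldscore_fitness,GOLD,higher_is_better
mmgbsa_dg_bind_gold,GOLD,lower_is_better
mbae_aset_gold,GOLD,lower_is_better
mbae_del_gold,GOLD,lower_is_better
glide_docking_score,Glide,lower_is_better
glide_ifdscore,Glide,lower_is_better
mmgbsa_dg_bind_glide,Glide,lower_is_better
mbae_aset_glide,Glide,lower_is_better
mbae_del_glide,Glide,lower_is_better
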
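name,mw_g_per_mol,pka,pka_kind,log_kow,log_kow_measured,specific_activity_ci_per_mmol,environmental_ng_per_l
propranolol,259.34,9.42,base,2.54,1.12,29.0,33
metoprolol,267.364,9.6,base,1.76,-0.90,29.7,410
atenolol,266.336,9.6,base,0.67,0.0015,7.3,940
formoterol,344.405,7.9;9.2,acid;base,1.93,0.41,18.5,NA
terbutaline,225.284,8.86;9.76,acid;base,1.25,1.2,29.0,97
ranitidine,314.4,8.08,base,1.47,NA,2.5,120
imipramine,280.407,9.4,base,4.39,0.14,48.5,NA
mannitol,182.172,NA,none,-3.1,NA,20.0,NA
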
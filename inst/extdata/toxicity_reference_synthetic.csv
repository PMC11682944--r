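compound,acute_oral_ld50_ug_per_bee,chronic_lc50_ug_per_bee_day,chronic_ldd50_ug_per_bee_day,source_note
boscalid,166,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
chlorantraniliprole,4,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
clothianidin,0.00368,NA,0.0014,synthetic placeholder; order of magnitude from public registrant summaries
coumaphos,4.6,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
difenoconazole,100,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
dimethoate,0.12,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
fenhexamid,102,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
flonicamid,53,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
fluopyram,110,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
flupyradifurone,1.2,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
imidacloprid,0.0037,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
linuron,97,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
mandipropamid,106,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
metconazole,85,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
napropamide,111,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
novaluron,121,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
omethoate,0.32,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
pyraclostrobin,73,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
pyrimethanil,100,NA,NA,synthetic placeholder; order of magnitude from public registrant summaries
thiamethoxam,0.005,0.0056,0.0047,synthetic placeholder; order of magnitude from public registrant summaries
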
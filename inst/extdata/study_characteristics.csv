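study_id,year,country,cases,controls,case_source,control_source,specimen,hwe_in_controls,quality_printed
Auranen,2005,UK-USA,1665,4241,mixed,population,blood_or_normal_tissue,TRUE,14
Beesley,2007,Australia,731,747,population_or_registry,population,blood_or_normal_tissue,TRUE,15
Quaye,2009,DK-UK-USA,1461,2299,mixed,population,blood_or_normal_tissue,TRUE,14
Webb,2005,Australia,1445,788,mixed,volunteers_or_blood_bank,mixed_blood_paraffin,TRUE,12
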
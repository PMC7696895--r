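id	name	formula	mass	status
HMDB0000056	beta-Alanine	C3H7NO2	89.0477	detected
HMDB0001310	D-Alanine	C3H7NO2	89.0477	detected
HMDB0000161	L-Alanine	C3H7NO2	89.0477	quantified
HMDB0031206	Ethyl carbamate	C3H7NO2	89.0477	detected
HMDB0000271	Sarcosine	C3H7NO2	89.0477	quantified
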
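class	compound	expected_ri	A	B	C	D
Pentoses	Xylose	1651	A		C
Pentoses	Ribose	1672		B		D
Pentoses	Arabitol	1711			C	D
Pentoses	Ribitol	1716	A	B
Hexoses	Fructose	1862		B	C
Hexoses	Mannose	1876	A			D
Hexoses	Galactose	1880	A		C
Hexoses	Glucose	1886		B		D
Sugar Derivatives	Sorbitol	1926	A			D
Sugar Derivatives	Glucuronic acid	1927	A		C
Sugar Derivatives	Glucosamine	1932	A	B
Sugar Derivatives	Galacturonic acid	1935		B		D
Sugar Derivatives	Gluconic acid	1996		B	C
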
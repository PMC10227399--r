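strain one	delta 9 tetrahydrocannabinol
strain one	myrcene
strain two	cbd
strain two	limonene
strain three	myrcene
strain three	pinene
strain four	linalool
strain five	limonene
strain six	cbd
strain six	pinene
strain seven	delta 9 tetrahydrocannabinol
strain eight	myrcene
strain nine	cbd
strain nine	linalool
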
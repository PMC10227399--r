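CBD	cbd	chemical
cannabidiol	cbd	chemical
CBDA	cannabidiolic acid	chemical
cannabidiolic acid	cannabidiolic acid	chemical
CBGA	cannabigerolic acid	chemical
cannabigerolic acid	cannabigerolic acid	chemical
THC	delta 9 tetrahydrocannabinol	chemical
delta-9-tetrahydrocannabinol	delta 9 tetrahydrocannabinol	chemical
tetrahydrocannabinol	delta 9 tetrahydrocannabinol	chemical
limonene	limonene	chemical
myrcene	myrcene	chemical
pinene	pinene	chemical
linalool	linalool	chemical
olivetolic acid	olivetolic acid	chemical
ribavirin	ribavirin	chemical
CBDAS	cbda synthase	gene
cannabidiolic acid synthase	cbda synthase	gene
THCAS	thca synthase	gene
tetrahydrocannabinolic acid synthase	thca synthase	gene
OLS	olivetol synthase	gene
olivetol synthase	olivetol synthase	gene
NLRP3 inflammasome	nlrp3 inflammasome	gene
RNase	rnase	gene
analgesic	analgesic	property
antinociceptive	antinociceptive	property
anti-inflammatory	anti inflammatory	property
antiviral	antiviral	property
antioxidant	antioxidant	property
anxiolytic	anxiolytic	property
sedative	sedative	property
volatile	volatile	property
pain	pain	property
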
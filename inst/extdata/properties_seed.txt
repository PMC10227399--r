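# seed list of therapeutic-property phrases, one per line
analgesic
anti-inflammatory
antiviral
antioxidant
anxiolytic
sedative
antiemetic
anticonvulsant
neuroprotective
antimicrobial
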
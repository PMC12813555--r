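# Opioid use disorder ICD codes (toy stand-in list; one code per line)
# ICD-10-CM
F11.20
F11.10
F11.90
# ICD-9-CM
304.00
304.70
305.50
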
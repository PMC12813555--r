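# Cancer-diagnosis ICD codes (toy stand-in list; one code per line)
# ICD-10-CM
C50.9
C61
C34.9
# ICD-9-CM
174.9
185
162.9
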
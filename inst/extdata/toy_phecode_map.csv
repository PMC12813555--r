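code,version,phecode
Y29510,ICD10,295.10
V29510,ICD9,295.10
Y29620,ICD10,296.20
V29620,ICD9,296.20
Y30010,ICD10,300.10
V30010,ICD9,300.10
Y31800,ICD10,318.00
V31800,ICD9,318.00
Y32740,ICD10,327.40
V32740,ICD9,327.40
Y33820,ICD10,338.20
V33820,ICD9,338.20
Y40110,ICD10,401.10
V40110,ICD9,401.10
Y49500,ICD10,495.00
V49500,ICD9,495.00
Y54010,ICD10,540.10
V54010,ICD9,540.10
Y76000,ICD10,760.00
V76000,ICD9,760.00
Y90001,ICD10,900.01
V90001,ICD9,900.01
Y90002,ICD10,900.02
V90002,ICD9,900.02
Y90003,ICD10,900.03
V90003,ICD9,900.03
Y90004,ICD10,900.04
V90004,ICD9,900.04
Y90005,ICD10,900.05
V90005,ICD9,900.05
Y90006,ICD10,900.06
V90006,ICD9,900.06
Y90007,ICD10,900.07
V90007,ICD9,900.07
Y90008,ICD10,900.08
V90008,ICD9,900.08
Y90009,ICD10,900.09
V90009,ICD9,900.09
Y90010,ICD10,900.10
V90010,ICD9,900.10
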
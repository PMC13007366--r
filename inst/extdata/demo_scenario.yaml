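populations:
- JPN
- SWE
sexes:
- male
- female
cohort_size: 6.0
baseline_date: '2017-04-01'
follow_up_years: 3.0
omega: 105.0
emigration_rate: 0.005
hazards:
  A:
    male:
      death:
        no_care: 0.0038
        home_care: 0.018
        care_home: 0.048
      death_slope:
        no_care: 0.115
        home_care: 0.065
        care_home: 0.045
      entry:
        no_home: 0.0085
        no_ch: 0.0013
        home_ch: 0.011
      entry_slope:
        no_home: 0.085
        no_ch: 0.085
        home_ch: 0.085
      recovery:
        home_no: 0.035
        ch_home: 0.006
        ch_no: 0.003
    female:
      death:
        no_care: 0.0017
        home_care: 0.009
        care_home: 0.027
      death_slope:
        no_care: 0.115
        home_care: 0.07
        care_home: 0.05
      entry:
        no_home: 0.013
        no_ch: 0.0018
        home_ch: 0.011
      entry_slope:
        no_home: 0.085
        no_ch: 0.085
        home_ch: 0.085
      recovery:
        home_no: 0.035
        ch_home: 0.006
        ch_no: 0.003
  B:
    male:
      death:
        no_care: 0.0036
        home_care: 0.023
        care_home: 0.062
      death_slope:
        no_care: 0.105
        home_care: 0.065
        care_home: 0.045
      entry:
        no_home: 0.007
        no_ch: 0.0026
        home_ch: 0.018
      entry_slope:
        no_home: 0.085
        no_ch: 0.085
        home_ch: 0.085
      recovery:
        home_no: 0.03
        ch_home: 0.006
        ch_no: 0.003
    female:
      death:
        no_care: 0.0016
        home_care: 0.0135
        care_home: 0.039
      death_slope:
        no_care: 0.105
        home_care: 0.07
        care_home: 0.05
      entry:
        no_home: 0.011
        no_ch: 0.0035
        home_ch: 0.018
      entry_slope:
        no_home: 0.085
        no_ch: 0.085
        home_ch: 0.085
      recovery:
        home_no: 0.03
        ch_home: 0.006
        ch_no: 0.003
age_dist:
  A:
    male:
      75-79: 0.4535
      80-84: 0.322
      85-89: 0.1599
      90-94: 0.0541
      95-99: 0.0094
      100+: 0.0011
    female:
      75-79: 0.3692
      80-84: 0.3044
      85-89: 0.1961
      90-94: 0.0953
      95-99: 0.0297
      100+: 0.0053
  B:
    male:
      75-79: 0.4614
      80-84: 0.2917
      85-89: 0.1676
      90-94: 0.0652
      95-99: 0.0132
      100+: 0.0009
    female:
      75-79: 0.3816
      80-84: 0.2798
      85-89: 0.2015
      90-94: 0.1037
      95-99: 0.0299
      100+: 0.0035
init_state:
  A:
    male:
      75-79:
        no_care: 0.932
        home_care: 0.055
        care_home: 0.013
      80-84:
        no_care: 0.862
        home_care: 0.108
        care_home: 0.03
      85-89:
        no_care: 0.74
        home_care: 0.195
        care_home: 0.065
      90-94:
        no_care: 0.59
        home_care: 0.269
        care_home: 0.141
      95-99:
        no_care: 0.473
        home_care: 0.304
        care_home: 0.223
      100+:
        no_care: 0.378
        home_care: 0.37
        care_home: 0.252
    female:
      75-79:
        no_care: 0.905
        home_care: 0.075
        care_home: 0.02
      80-84:
        no_care: 0.768
        home_care: 0.176
        care_home: 0.056
      85-89:
        no_care: 0.571
        home_care: 0.29
        care_home: 0.139
      90-94:
        no_care: 0.41
        home_care: 0.33
        care_home: 0.26
      95-99:
        no_care: 0.317
        home_care: 0.308
        care_home: 0.375
      100+:
        no_care: 0.28
        home_care: 0.248
        care_home: 0.472
  B:
    male:
      75-79:
        no_care: 0.941
        home_care: 0.039
        care_home: 0.02
      80-84:
        no_care: 0.854
        home_care: 0.096
        care_home: 0.05
      85-89:
        no_care: 0.713
        home_care: 0.187
        care_home: 0.1
      90-94:
        no_care: 0.521
        home_care: 0.295
        care_home: 0.184
      95-99:
        no_care: 0.333
        home_care: 0.366
        care_home: 0.301
      100+:
        no_care: 0.214
        home_care: 0.383
        care_home: 0.403
    female:
      75-79:
        no_care: 0.922
        home_care: 0.055
        care_home: 0.023
      80-84:
        no_care: 0.789
        home_care: 0.143
        care_home: 0.068
      85-89:
        no_care: 0.589
        home_care: 0.261
        care_home: 0.15
      90-94:
        no_care: 0.371
        home_care: 0.352
        care_home: 0.277
      95-99:
        no_care: 0.211
        home_care: 0.355
        care_home: 0.434
      100+:
        no_care: 0.144
        home_care: 0.279
        care_home: 0.577
seed: 42
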
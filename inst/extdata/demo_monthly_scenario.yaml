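frequency: monthly
start: 2015-01
end: 2021-12
seed: 1
exposure:
  start: 2020-12
  end: 2021-12
shock_windows: []
groups:
  advantaged:
    name: advantaged
    intercept: 7.649692623711514
    trend:
    - 0.06
    - -0.02
    exposure_effect: 0.048790164169432
    seasonal:
    - 0.0
    - -0.019545612321008
    - -0.024404198584548
    - -0.013273904524948
    - 0.010862916553
    - 0.041538822933608
    - 0.070534230275097
    - 0.090079842596104
    - 0.094938428859645
    - 0.083808134800045
    - 0.059671313722096
    - 0.028995407341489
  middle:
    name: middle
    intercept: 8.070906088787819
    trend:
    - -0.08
    - 0.02
    exposure_effect: 0.009950330853168
    seasonal:
    - 0.0
    - -0.019545612321008
    - -0.024404198584548
    - -0.013273904524948
    - 0.010862916553
    - 0.041538822933608
    - 0.070534230275097
    - 0.090079842596104
    - 0.094938428859645
    - 0.083808134800045
    - 0.059671313722096
    - 0.028995407341489
  disadvantaged:
    name: disadvantaged
    intercept: 7.24422751560335
    trend:
    - -0.15
    - 0.04
    exposure_effect: -0.030459207484709
    seasonal:
    - 0.0
    - -0.019545612321008
    - -0.024404198584548
    - -0.013273904524948
    - 0.010862916553
    - 0.041538822933608
    - 0.070534230275097
    - 0.090079842596104
    - 0.094938428859645
    - 0.083808134800045
    - 0.059671313722096
    - 0.028995407341489
  missing:
    name: missing
    intercept: 5.857933154483459
    trend:
    - 0.0
    - 0.0
    exposure_effect: 0.0
    seasonal:
    - 0.0
    - -0.019545612321008
    - -0.024404198584548
    - -0.013273904524948
    - 0.010862916553
    - 0.041538822933608
    - 0.070534230275097
    - 0.090079842596104
    - 0.094938428859645
    - 0.083808134800045
    - 0.059671313722096
    - 0.028995407341489
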
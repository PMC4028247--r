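tool
pred01
pred02
pred03
pred04
pred05
pred06
pred07
pred08
pred09
pred10
pred11
pred12
pred13
pred14
pred15
pred16
pred17
pred18
pred19
pred20
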
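note: SYNTHETIC fixture: hand-written, openly fictional wiring;
        demonstrates protocol mechanics, not biology.
on: SOX2
off: LET7
locked_off: MECP2
activation: elliott
tolerance: 0.001
max_iterations: 1000
overtraining_check: TRUE
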
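# paper-scale configuration (slow: larger network, longer budgets)
nInputs: 1000
trials: 10
maxEpochs: 2000
alphaMax: 8
seed: 1
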
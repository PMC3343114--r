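# desk-scale configuration for the standard-perceptron correlation sweep
nInputs: 200
trials: 10
maxEpochs: 500
seed: 1
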
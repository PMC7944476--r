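# Two-class demonstration run: control vs severe TBI with cardiolipin at
# 50% of the control level. All fields mirror cohortConfig() /
# somTrainConfig(); the seed is mandatory.
seed: 1
input:
  synthetic:
    nPerClass: 10
    classes: [control, sTBI]
    nAccumulations: 15
    coefficientCV: 0.15
    noiseSD: 0.01
    spikeRate: 0.2
    baselineAmplitude: 0.5
    axis: {from: 600, to: 1800, by: 1}
preprocess:
  spikeThreshold: 8
  baselineNodes: 11
  baselineIterations: 20
  normalization: none
split:
  trainFraction: 0.7
train:
  gridWidth: 10
  gridHeight: 10
  nEpochs: 100
  normalization: vector
unmix:
  includeOffset: true
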
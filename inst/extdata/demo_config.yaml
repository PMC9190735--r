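# Demo-scale configuration for the mvpatime pipeline. Analysis constants
# are the canonical ones; the simulation is reduced so a full run takes
# minutes. Raise the design/analysis fields for full-scale runs
# (48 objects, 8 auditory / 6 visual runs, 5 reps, 100 repetitions,
# 10000 permutations, 63 channels, 1000 Hz acquisition).
participants: 12
seed: 1
design:
  nObjects: 8
  nDims: 3
  runsPerModality:
    auditory: 2
    visual: 2
  repsPerStimPerRun: 3
  onebackFraction: 0.20
  epochWindow: [-200, 800]
  fsRaw: 200
  fsTarget: 200
  nChannels: 32
signal:
  objectOnsetMs: 75
  categoryOnsetMs: 305
  rampMs: 20
  snr: 1.5
  modalityCoding: orthogonal
  noiseRho: 0.3
  noiseSd: 1
preprocess:
  zThreshold: 20
analysis:
  schemes: [object, category, crossmodal]
  nRepetitions: 20
  nGroups: 3
  cost: 1
inference:
  nPermutations: 1000
  nBootstrap: 1000
  alpha: 0.05
  chance: 50
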
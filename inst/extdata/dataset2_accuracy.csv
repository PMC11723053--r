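subject,60 EEG,60 EEG + 2 EOG,2 EOG,3 EEG,3 EEG + 2 EOG
S1,35.7,44.6,51.7,45.5,58
S2,47.3,57.1,49.1,41.9,56.2
S3,40.1,43.7,31.2,41,41
S4,66.9,79.4,62.5,62.5,67.8
S5,64.2,68.7,58.9,73.2,73.2
S6,45,48,50,44,42
S7,64.2,70.5,48.2,52.6,53.5
S8,66.9,64.2,59.8,73.2,73.2
S9,63.3,62.5,58.9,58.9,66
S10,81.2,87.5,81.2,55.3,79.4
Mean,57.4,62.6,55.1,54.8,61
Median,63.75,63.35,55.3,53.95,62
StandardDeviation,13.784,13.89,12.16,11.48,12.47
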
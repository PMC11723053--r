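subject,22 EEG,22 EEG + 3 EOG,3 EOG,3 EEG,3 EEG + 3 EOG
S1,81.8,85.3,62,65.5,79.3
S2,65.5,75.8,63.7,48.2,71.5
S3,91.3,89.6,51.7,82.7,83.6
S4,81,86.2,62.9,59.4,71.5
S5,83.6,95.6,94.8,69.8,95.6
S6,77.5,80.1,62.9,55.1,71.5
S7,92.2,91.3,90.5,85.3,92.2
S8,90.5,91.3,86.2,76.7,91.3
S9,93.1,96.5,75.8,81,90.5
Mean,84,87.9,72.2,69.3,83
Median,83.6,89.6,63.7,69.8,83.6
StandardDeviation,8.46,6.46,14.23,12.41,9.3
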
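subject,acc_fnirs,sens_fnirs,spec_fnirs,acc_combined,sens_combined,spec_combined,n_trials
2,74.8,72.3,77.2,81.7,82.1,81.3,46
3,85.5,85.7,85.2,87.7,85.6,89.8,48
4,91.7,88.7,94.8,98.8,99.6,98.0,60
5,71.7,72.8,70.6,89.2,84.7,93.7,46
6,90.3,87.2,93.5,94.2,93.8,94.6,30
7,62.4,62.8,61.9,79.6,77.3,81.9,58
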
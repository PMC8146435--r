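method,class,recall,accuracy,specificity,precision,f
KNN,D0,97.79231,98.68905,99.08583,97.93103,97.86162
KNN,D1,93.26091,96.15259,97.2771,93.0164,93.1385
KNN,D2,95.034,98.22611,99.05668,96.32533,95.67531
KNN,D3,94.51789,97.22341,98.03675,93.53711,94.02494
RBF,D0,99.25074,82.01636,77.65825,52.90485,69.01942
RBF,D1,48.88534,68.92509,89.98789,83.69179,61.71957
RBF,D2,67.96758,85.79975,95.04128,87.65964,76.56776
RBF,D3,69.92255,77.64791,78.85736,34.11347,45.85529
LDA,D0,98.48341,98.15457,98.01794,95.37975,96.90674
LDA,D1,94.00677,96.82879,97.94545,94.76578,94.38475
LDA,D2,95.08951,98.40386,99.27126,97.15499,96.11116
LDA,D3,95.00488,97.91817,98.82235,96.15949,95.57869
ANN-ICA,D0,97.63083,98.60188,99.02519,97.7608,97.69577
ANN-ICA,D1,94.19536,96.94436,98.02753,94.95371,94.57302
ANN-ICA,D2,96.70631,98.65802,99.15395,96.67157,96.68894
ANN-ICA,D3,96.1103,97.94602,98.49586,95.0344,95.56932
ANN-HS,D0,97.64972,98.65699,99.09759,97.93103,97.79018
ANN-HS,D1,94.18942,96.93468,98.01631,94.92587,94.55621
ANN-HS,D2,96.58156,98.62237,99.1414,96.62257,96.60206
ANN-HS,D3,96.07512,97.87916,98.41753,94.76934,95.41777
MV,D0,97.58693,98.43423,98.80345,97.2632,97.4248
MV,D1,92.23028,96.365,98.04546,95.0442,93.6161
MV,D2,96.66907,98.57246,99.05725,96.31227,96.49034
MV,D3,96.17016,97.57179,97.98271,93.32281,94.72509
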
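method,actual,D0,D1,D2,D3
KNN,D0,44872,948,0,0
KNN,D1,1013,40091,768,1229
KNN,D2,0,430,29490,695
KNN,D3,0,1519,773,33172
RBF,D0,24241,16740,2950,1889
RBF,D1,169,36072,4155,2705
RBF,D2,0,3168,26837,610
RBF,D3,14,17809,5543,12098
LDA,D0,43703,1751,366,0
LDA,D1,673,40845,266,1317
LDA,D2,0,395,29744,476
LDA,D3,0,458,904,34102
ANN-ICA,D0,44794,997,29,0
ANN-ICA,D1,1087,40926,133,955
ANN-ICA,D2,0,610,29596,409
ANN-ICA,D3,0,915,846,33703
ANN-HS,D0,44872,899,49,0
ANN-HS,D1,1079,40914,151,957
ANN-HS,D2,1,617,29581,416
ANN-HS,D3,0,1008,847,33609
MV,D0,44566,1157,96,1
MV,D1,1094,40965,132,910
MV,D2,8,714,29486,407
MV,D3,0,1580,788,33096
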
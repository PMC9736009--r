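honey,syrup,classifier,accuracy
Q,F,lda,93.2
Q,G,lda,100
Q,M,lda,85
GS,F,lda,96.2
GS,G,lda,93.2
GS,M,lda,84.2
Q,F,svm,91.2
Q,G,svm,100
Q,M,svm,89
GS,F,svm,95.2
GS,G,svm,96
GS,M,svm,85
Q,F,nn,87.8
Q,G,nn,100
Q,M,nn,83.8
GS,F,nn,93.5
GS,G,nn,95.2
GS,M,nn,84.5
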
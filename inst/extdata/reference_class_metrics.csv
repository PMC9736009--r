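honey,syrup,class,classifier,precision,recall,specificity
Q,F,90,lda,98.9,93,99.6
Q,F,80,lda,91.9,91,97.3
Q,F,70,lda,97.9,97,99
Q,F,60,lda,85,92,94.6
Q,F,90,svm,98,98,99
Q,F,80,svm,84.5,82,95
Q,F,70,svm,98.9,98,99.6
Q,F,60,svm,83.6,87,94.3
Q,F,90,nn,96.8,93,99
Q,F,80,nn,78,82,92
Q,F,70,nn,97,97,99
Q,F,60,nn,79.7,79,93
GS,F,90,lda,97,100,99
GS,F,80,lda,94.8,92,98
GS,F,70,lda,100,98,100
GS,F,60,lda,93,95,97.6
GS,F,90,svm,98,99,99.3
GS,F,80,svm,92,92,97.3
GS,F,70,svm,98.9,97,99.6
GS,F,60,svm,92,93,97
GS,F,90,nn,99,100,99
GS,F,80,nn,97,80,96
GS,F,70,nn,100,97,100
GS,F,60,nn,88,89,96
Q,G,90,lda,100,100,100
Q,G,80,lda,100,100,100
Q,G,70,lda,100,100,100
Q,G,60,lda,100,100,100
Q,G,90,svm,100,100,100
Q,G,80,svm,100,100,100
Q,G,70,svm,100,100,100
Q,G,60,svm,100,100,100
Q,G,90,nn,100,100,100
Q,G,80,nn,100,100,100
Q,G,70,nn,100,100,100
Q,G,60,nn,100,100,100
GS,G,90,lda,86,87,95
GS,G,80,lda,100,100,100
GS,G,70,lda,86.8,86,95.6
GS,G,60,lda,100,100,100
GS,G,90,svm,90,94,96.6
GS,G,80,svm,100,100,100
GS,G,70,svm,93.7,90,98
GS,G,60,svm,100,100,100
GS,G,90,nn,88.5,93,96
GS,G,80,nn,100,96,100
GS,G,70,nn,93,93,97.6
GS,G,60,nn,99.7,99,100
Q,M,90,lda,89,83,93.6
Q,M,80,lda,75,76,91.6
Q,M,70,lda,77,82,92
Q,M,60,lda,100,100,100
Q,M,90,svm,91,91,97
Q,M,80,svm,80.9,85,93
Q,M,70,svm,85,81,95
Q,M,60,svm,100,100,100
Q,M,90,nn,89.6,87,96.6
Q,M,80,nn,69,78,88.6
Q,M,70,nn,77,71,93
Q,M,60,nn,100,99,100
GS,M,90,lda,75,85,92
GS,M,80,lda,84,84,94.6
GS,M,70,lda,79,69,94
GS,M,60,lda,100,100,100
GS,M,90,svm,79.4,93,92
GS,M,80,svm,81.8,72,94.6
GS,M,70,svm,78.9,75,93
GS,M,60,svm,100,100,100
GS,M,90,nn,84.6,83,94.6
GS,M,80,nn,80,80,93
GS,M,70,nn,74.7,77,91
GS,M,60,nn,100,98,100
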
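subject,scheme,classifier,accuracy,channel
S1,loocv,lda,84,T7
S1,kfold10,lda,86,T7
S2,loocv,lda,98,T7
S2,kfold10,lda,98,T7
S3,loocv,lda,68,T8
S3,kfold10,lda,68,T8
S4,loocv,lda,92,T7
S4,kfold10,lda,96,T7
S5,loocv,lda,70,T7
S5,kfold10,lda,68,AF3
S6,loocv,lda,74,T8
S6,kfold10,lda,64,PZ
S7,loocv,lda,84,AF3
S7,kfold10,lda,82,T7
S8,loocv,lda,68,PZ
S8,kfold10,lda,70,PZ
S9,loocv,lda,98,T7
S9,kfold10,lda,98,T7
S10,loocv,lda,82,AF4
S10,kfold10,lda,78,AF4
S11,loocv,lda,82,AF4
S11,kfold10,lda,76,AF4
S12,loocv,lda,94,PZ
S12,kfold10,lda,92,PZ
S13,loocv,lda,98,T8
S13,kfold10,lda,98,T8
S14,loocv,lda,80,T7
S14,kfold10,lda,80,T7
S15,loocv,lda,88,AF4
S15,kfold10,lda,88,AF4
S16,loocv,lda,76,AF4
S16,kfold10,lda,82,AF4
S17,loocv,lda,82,PZ
S17,kfold10,lda,80,PZ
S18,loocv,lda,88,T8
S18,kfold10,lda,86,AF3
S19,loocv,lda,66,T8
S19,kfold10,lda,68,AF3
S20,loocv,lda,72,PZ
S20,kfold10,lda,66,PZ
S21,loocv,lda,86,T8
S21,kfold10,lda,82,T8
S22,loocv,lda,90,PZ
S22,kfold10,lda,90,T7
S23,loocv,lda,62,PZ
S23,kfold10,lda,66,PZ
S24,loocv,lda,72,T7
S24,kfold10,lda,74,T7
S25,loocv,lda,98,PZ
S25,kfold10,lda,98,PZ
S26,loocv,lda,90,T8
S26,kfold10,lda,90,T8
S27,loocv,lda,92,PZ
S27,kfold10,lda,90,AF3
S1,losocv,svm_rbf,64,AF3
S2,losocv,svm_rbf,60,PZ
S3,losocv,svm_rbf,66,T7
S4,losocv,svm_rbf,52,PZ
S5,losocv,svm_rbf,66,AF4
S6,losocv,svm_rbf,68,T8
S7,losocv,svm_rbf,76,T8
S8,losocv,svm_rbf,62,PZ
S9,losocv,svm_rbf,34,T7
S10,losocv,svm_rbf,76,AF4
S11,losocv,svm_rbf,60,T7
S12,losocv,svm_rbf,80,PZ
S13,losocv,svm_rbf,68,AF4
S14,losocv,svm_rbf,78,T7
S15,losocv,svm_rbf,54,AF4
S16,losocv,svm_rbf,72,AF4
S17,losocv,svm_rbf,62,T7
S18,losocv,svm_rbf,80,PZ
S19,losocv,svm_rbf,58,AF4
S20,losocv,svm_rbf,76,PZ
S21,losocv,svm_rbf,64,T8
S22,losocv,svm_rbf,62,T7
S23,losocv,svm_rbf,64,PZ
S24,losocv,svm_rbf,50,PZ
S25,losocv,svm_rbf,68,T7
S26,losocv,svm_rbf,58,AF4
S27,losocv,svm_rbf,52,T7
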
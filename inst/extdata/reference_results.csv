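feature,optimizer,acc_mean,acc_sd,acc_best,nch_mean,nch_sd,nch_best,n_runs
time,GA,84.75,1.44,86.50,16.80,2.66,13,10
time,PSO,83.75,1.18,86.00,18.10,2.77,15,10
time,pGAPSO-I,84.90,1.15,86.50,10.10,3.67,8,10
time,pGAPSO-II,84.65,0.67,86.00,9.30,2.11,11,10
time,pGAPSO-III,84.65,1.06,86.50,7.40,2.27,9,10
time,sPSOGA,83.25,1.59,85.50,18.60,4.06,19,10
time,sGAPSO,84.65,1.42,86.50,15.70,2.54,15,10
fc,GA,82.30,1.32,84.50,23.30,2.91,24,10
fc,PSO,79.40,1.39,81.50,23.60,3.95,17,10
fc,pGAPSO-I,81.25,1.46,83.50,17.20,4.87,16,10
fc,pGAPSO-II,81.45,1.46,83.50,13.50,3.98,11,10
fc,pGAPSO-III,80.75,2.54,84.00,19.80,5.05,15,10
fc,sPSOGA,80.75,1.96,85.00,20.40,3.37,19,10
fc,sGAPSO,81.80,1.27,84.00,24.10,3.03,21,10
wavelet,GA,84.50,1.65,87.00,13.80,2.62,16,10
wavelet,PSO,82.00,1.11,84.50,14.90,1.97,17,10
wavelet,pGAPSO-I,82.35,0.75,83.50,9.90,1.45,9,10
wavelet,pGAPSO-II,82.50,1.37,84.50,9.50,1.43,11,10
wavelet,pGAPSO-III,81.85,0.71,83.00,9.10,2.23,10,10
wavelet,sPSOGA,81.45,1.34,85.00,15.90,2.85,15,10
wavelet,sGAPSO,83.20,1.53,85.00,15.40,2.84,13,10
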
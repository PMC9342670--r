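feature,optimizer,channels
time,GA,3 5 12 14 19 25 31 32 34 39 41 43 48
time,PSO,3 5 14 19 27 30 31 34 39 40 41 43 44 45 47
time,pGAPSO-I,3 4 19 26 30 39 47 51
time,pGAPSO-II,2 6 16 19 30 37 39 43 44 47 50
time,pGAPSO-III,4 13 14 19 20 31 39 47 48
time,sPSOGA,2 4 6 7 8 10 16 18 19 25 31 34 36 37 39 43 44 47 50
time,sGAPSO,2 5 8 12 16 19 20 24 25 39 43 44 47 48 50
fc,GA,2 5 7 8 11 12 13 15 17 18 19 20 22 24 25 27 30 31 36 45 48 50 51 52
fc,PSO,2 5 6 7 9 10 12 13 15 17 20 22 25 45 46 47 51
fc,pGAPSO-I,2 7 9 13 14 15 16 17 20 25 26 30 36 45 51 52
fc,pGAPSO-II,2 5 6 8 13 15 17 19 20 30 45
fc,pGAPSO-III,2 4 7 12 14 15 16 17 25 26 31 45 48 50 51
fc,sPSOGA,2 7 8 9 11 12 13 15 16 17 18 19 20 25 28 30 45 49 50
fc,sGAPSO,2 5 7 8 9 11 12 13 15 17 18 19 20 25 30 42 45 46 48 50 51
wavelet,GA,1 3 6 7 9 10 13 16 19 29 30 32 34 39 45 48
wavelet,PSO,1 2 6 8 9 11 14 16 19 24 29 30 32 34 39 45 48
wavelet,pGAPSO-I,3 6 7 10 19 34 39 46 48
wavelet,pGAPSO-II,1 3 6 19 27 30 32 35 39 45 48
wavelet,pGAPSO-III,1 2 6 15 19 30 39 45 47 48
wavelet,sPSOGA,1 3 6 9 10 13 19 26 30 32 34 39 40 45 48
wavelet,sGAPSO,1 3 6 9 12 13 24 29 30 32 39 45 48
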
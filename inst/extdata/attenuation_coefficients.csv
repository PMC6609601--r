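material,energy_kev,mu_rho_cm2_g,mu_en_rho_cm2_g
aluminum,5,193.4,184.9
aluminum,6,115.3,110.1
aluminum,8,50.33,47.94
aluminum,10,26.23,24.63
aluminum,15,7.955,7.287
aluminum,20,3.441,3.094
aluminum,30,1.128,0.8778
aluminum,40,0.5685,0.3601
aluminum,50,0.3681,0.1840
aluminum,60,0.2778,0.1099
aluminum,80,0.2018,0.05511
aluminum,100,0.1704,0.03794
aluminum,150,0.1378,0.02827
air,5,40.27,39.31
air,6,23.41,22.70
air,8,9.921,9.446
air,10,5.120,4.742
air,15,1.614,1.334
air,20,0.7779,0.5389
air,30,0.3538,0.1537
air,40,0.2485,0.06833
air,50,0.2080,0.04098
air,60,0.1875,0.03041
air,80,0.1662,0.02407
air,100,0.1541,0.02325
air,150,0.1356,0.02496
water,5,42.58,41.76
water,6,24.64,24.05
water,8,10.37,9.915
water,10,5.329,4.944
water,15,1.673,1.374
water,20,0.8096,0.5503
water,30,0.3756,0.1557
water,40,0.2683,0.06947
water,50,0.2269,0.04223
water,60,0.2059,0.03190
water,80,0.1837,0.02597
water,100,0.1707,0.02546
water,150,0.1505,0.02764
soft_tissue,5,42.05,41.17
soft_tissue,6,24.36,23.76
soft_tissue,8,10.28,9.824
soft_tissue,10,5.356,4.964
soft_tissue,15,1.693,1.396
soft_tissue,20,0.8205,0.5611
soft_tissue,30,0.3783,0.1610
soft_tissue,40,0.2685,0.07184
soft_tissue,50,0.2262,0.04305
soft_tissue,60,0.2048,0.03224
soft_tissue,80,0.1823,0.02601
soft_tissue,100,0.1693,0.02538
soft_tissue,150,0.1492,0.02743
bone,5,219.0,209.0
bone,6,130.0,124.0
bone,8,56.00,53.40
bone,10,28.51,26.80
bone,15,9.032,8.388
bone,20,4.001,3.601
bone,30,1.331,1.070
bone,40,0.6655,0.4507
bone,50,0.4242,0.2336
bone,60,0.3148,0.1400
bone,80,0.2229,0.06896
bone,100,0.1855,0.04585
bone,150,0.1480,0.03183
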
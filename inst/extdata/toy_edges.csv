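origin,destination,weight
c0_0,c0_1,7.351
c0_0,c1_0,8.653
c0_0,c1_1,11.463
c0_0,c1_2,8.276
c0_0,c2_1,9.313
c0_0,c2_2,9.249
c0_1,c0_2,12.224
c0_1,c0_3,7.04
c0_1,c1_0,8.063
c0_1,c1_1,14.43
c0_1,c1_2,18.157
c0_1,c1_3,9.359
c0_1,c2_1,15.608
c0_1,c2_2,17.06
c0_1,c2_3,8.667
c0_1,c3_2,8.073
c0_2,c0_1,10.5
c0_2,c0_3,10.07
c0_2,c1_1,15.762
c0_2,c1_2,20.735
c0_2,c1_3,21.538
c0_2,c2_0,7.07
c0_2,c2_1,14.75
c0_2,c2_2,28.462
c0_2,c2_3,17.603
c0_2,c3_1,10.427
c0_2,c3_2,9.877
c0_3,c0_2,11.762
c0_3,c0_4,7.27
c0_3,c1_1,8.42
c0_3,c1_2,19.426
c0_3,c1_3,15.003
c0_3,c1_4,10.028
c0_3,c2_2,16.435
c0_3,c2_3,18.001
c0_3,c3_2,9.499
c0_4,c0_3,10.375
c0_4,c1_2,8.701
c0_4,c1_3,8.026
c0_4,c1_4,7.215
c0_4,c2_2,7.018
c1_0,c1_1,15.515
c1_0,c1_2,11.639
c1_0,c2_0,10.326
c1_0,c2_1,19.885
c1_0,c2_2,14.031
c1_0,c2_3,8.14
c1_0,c3_1,8.155
c1_0,c3_2,10.601
c1_1,c0_0,7.934
c1_1,c0_1,21.996
c1_1,c0_2,16.091
c1_1,c0_3,9.993
c1_1,c1_0,12.453
c1_1,c1_2,36.348
c1_1,c1_3,28.779
c1_1,c1_4,7.342
c1_1,c2_0,13.449
c1_1,c2_1,20.435
c1_1,c2_2,39.537
c1_1,c2_3,18.601
c1_1,c3_0,8.909
c1_1,c3_1,25.28
c1_1,c3_2,19.752
c1_1,c3_3,11.829
c1_2,c0_0,8.165
c1_2,c0_1,13.69
c1_2,c0_2,26.867
c1_2,c0_3,13.366
c1_2,c1_0,11.889
c1_2,c1_1,43.126
c1_2,c1_3,43.868
c1_2,c1_4,11.355
c1_2,c2_0,13.89
c1_2,c2_1,32.115
c1_2,c2_2,60.731
c1_2,c2_3,36.404
c1_2,c2_4,13.766
c1_2,c3_1,17.165
c1_2,c3_2,29.974
c1_2,c3_3,22.523
c1_2,c4_2,7.322
c1_3,c0_1,10.85
c1_3,c0_2,17.574
c1_3,c0_3,20.037
c1_3,c0_4,7.561
c1_3,c1_0,9.043
c1_3,c1_1,12.51
c1_3,c1_2,36.68
c1_3,c1_4,17.139
c1_3,c2_1,20.582
c1_3,c2_2,45.356
c1_3,c2_3,30.017
c1_3,c2_4,13.49
c1_3,c3_1,14.095
c1_3,c3_2,21.524
c1_3,c3_3,15.624
c1_3,c3_4,9.393
c1_3,c4_2,7.419
c1_4,c0_2,8.352
c1_4,c0_3,7.241
c1_4,c0_4,7.377
c1_4,c1_2,14.524
c1_4,c1_3,20.122
c1_4,c2_1,8.85
c1_4,c2_2,15.169
c1_4,c2_3,21.878
c1_4,c2_4,16.339
c1_4,c3_2,8.869
c1_4,c3_3,10.279
c2_0,c0_1,8.277
c2_0,c0_2,7.26
c2_0,c1_0,10.479
c2_0,c1_1,18.983
c2_0,c1_2,11.888
c2_0,c1_3,7.758
c2_0,c2_1,28.5
c2_0,c2_2,25.439
c2_0,c2_3,9.59
c2_0,c3_0,8.58
c2_0,c3_1,18.574
c2_0,c3_2,14.38
c2_0,c3_3,8.397
c2_1,c0_1,10.042
c2_1,c0_2,13.927
c2_1,c0_3,8.081
c2_1,c1_0,17.582
c2_1,c1_1,33.103
c2_1,c1_2,26.535
c2_1,c1_3,15.733
c2_1,c2_0,22.501
c2_1,c2_2,46.799
c2_1,c2_3,18.856
c2_1,c3_0,14.385
c2_1,c3_1,39.13
c2_1,c3_2,36.297
c2_1,c3_3,24.222
c2_1,c4_1,10.168
c2_1,c4_2,10.332
c2_1,c4_3,7.354
c2_2,c0_0,7.55
c2_2,c0_1,9.907
c2_2,c0_2,18.501
c2_2,c0_3,15.771
c2_2,c1_0,12.144
c2_2,c1_1,37.294
c2_2,c1_2,64.227
c2_2,c1_3,25.427
c2_2,c1_4,8.824
c2_2,c2_0,16.211
c2_2,c2_1,57.016
c2_2,c2_3,43.696
c2_2,c2_4,14.816
c2_2,c3_0,14.031
c2_2,c3_1,44.457
c2_2,c3_2,54.135
c2_2,c3_3,31.746
c2_2,c3_4,13.086
c2_2,c4_1,14.746
c2_2,c4_2,17.044
c2_2,c4_3,8.719
c2_3,c0_1,12.974
c2_3,c0_2,11.09
c2_3,c0_3,10.902
c2_3,c1_0,7.554
c2_3,c1_1,16.283
c2_3,c1_2,28.013
c2_3,c1_3,35.686
c2_3,c1_4,15.904
c2_3,c2_0,7.192
c2_3,c2_1,43.711
c2_3,c2_2,51.234
c2_3,c2_4,18.259
c2_3,c3_0,7.039
c2_3,c3_1,12.559
c2_3,c3_2,32.203
c2_3,c3_3,34.875
c2_3,c3_4,13.013
c2_3,c4_2,15.082
c2_3,c4_3,8.14
c2_4,c1_1,7.579
c2_4,c1_2,17.136
c2_4,c1_3,24.34
c2_4,c1_4,9.331
c2_4,c2_1,8.076
c2_4,c2_2,26.84
c2_4,c2_3,25.4
c2_4,c3_1,8.685
c2_4,c3_2,12.776
c2_4,c3_3,12.043
c2_4,c3_4,10.595
c2_4,c4_2,7.318
c3_0,c1_1,10.585
c3_0,c1_2,10.733
c3_0,c2_0,11.504
c3_0,c2_1,17.847
c3_0,c2_2,15.493
c3_0,c2_3,8.159
c3_0,c3_1,18.413
c3_0,c3_2,13.183
c3_0,c3_3,11.189
c3_0,c4_1,7.85
c3_0,c4_2,7.107
c3_1,c0_2,7.686
c3_1,c1_0,8.432
c3_1,c1_1,20.756
c3_1,c1_2,23.588
c3_1,c1_3,9.439
c3_1,c2_0,17.464
c3_1,c2_1,33.776
c3_1,c2_2,35.888
c3_1,c2_3,15.122
c3_1,c3_0,23.182
c3_1,c3_2,42.86
c3_1,c3_3,18.601
c3_1,c4_0,8.298
c3_1,c4_1,10.373
c3_1,c4_2,16.438
c3_1,c4_3,8.235
c3_2,c0_1,8.105
c3_2,c0_2,8.354
c3_2,c0_3,7.229
c3_2,c1_0,8.407
c3_2,c1_1,18.771
c3_2,c1_2,20.852
c3_2,c1_3,15.766
c3_2,c2_0,13.605
c3_2,c2_1,24.635
c3_2,c2_2,72.289
c3_2,c2_3,33.923
c3_2,c2_4,11.066
c3_2,c3_0,13.01
c3_2,c3_1,32.369
c3_2,c3_3,45.799
c3_2,c3_4,8.353
c3_2,c4_1,19.493
c3_2,c4_2,33.891
c3_2,c4_3,19.606
c3_3,c0_2,7.945
c3_3,c1_1,11.808
c3_3,c1_2,17.493
c3_3,c1_3,24.41
c3_3,c1_4,8.058
c3_3,c2_1,22.079
c3_3,c2_2,34.218
c3_3,c2_3,28.766
c3_3,c2_4,14.115
c3_3,c3_1,16.519
c3_3,c3_2,29.328
c3_3,c3_4,18.615
c3_3,c4_2,18.222
c3_3,c4_3,18.876
c3_3,c4_4,7.533
c3_4,c1_3,10.256
c3_4,c2_1,11.658
c3_4,c2_2,14.208
c3_4,c2_3,22.572
c3_4,c2_4,12.007
c3_4,c3_2,13.845
c3_4,c3_3,19.05
c3_4,c4_3,9.387
c4_0,c2_1,9.162
c4_0,c2_2,7.532
c4_0,c3_1,12.438
c4_1,c1_1,7.711
c4_1,c2_1,12.644
c4_1,c2_2,14.79
c4_1,c2_3,9.123
c4_1,c3_0,7.023
c4_1,c3_1,17.544
c4_1,c3_2,16.641
c4_1,c3_3,7.013
c4_1,c4_0,7.659
c4_1,c4_2,9.989
c4_1,c4_3,7.185
c4_2,c1_1,11.246
c4_2,c1_2,9.841
c4_2,c2_1,11.888
c4_2,c2_2,18.855
c4_2,c2_3,15.848
c4_2,c3_1,24.643
c4_2,c3_2,31.508
c4_2,c3_3,15.759
c4_2,c4_1,13.516
c4_2,c4_3,12.698
c4_3,c1_2,10.542
c4_3,c1_3,10.416
c4_3,c2_2,16.794
c4_3,c2_3,14.213
c4_3,c2_4,7.482
c4_3,c3_1,7.165
c4_3,c3_2,15.891
c4_3,c3_3,15.888
c4_3,c3_4,9.675
c4_3,c4_1,7.237
c4_3,c4_2,16.952
c4_4,c2_2,10.532
c4_4,c2_3,8.507
c4_4,c3_2,8.035
c4_4,c3_3,9.688
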
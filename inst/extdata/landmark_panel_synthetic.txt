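LMG0001
LMG0002
LMG0003
LMG0004
LMG0005
LMG0006
LMG0007
LMG0008
LMG0009
LMG0010
LMG0011
LMG0012
LMG0013
LMG0014
LMG0015
LMG0016
LMG0017
LMG0018
LMG0019
LMG0020
LMG0021
LMG0022
LMG0023
LMG0024
LMG0025
LMG0026
LMG0027
LMG0028
LMG0029
LMG0030
LMG0031
LMG0032
LMG0033
LMG0034
LMG0035
LMG0036
LMG0037
LMG0038
LMG0039
LMG0040
LMG0041
LMG0042
LMG0043
LMG0044
LMG0045
LMG0046
LMG0047
LMG0048
LMG0049
LMG0050
LMG0051
LMG0052
LMG0053
LMG0054
LMG0055
LMG0056
LMG0057
LMG0058
LMG0059
LMG0060
LMG0061
LMG0062
LMG0063
LMG0064
LMG0065
LMG0066
LMG0067
LMG0068
LMG0069
LMG0070
LMG0071
LMG0072
LMG0073
LMG0074
LMG0075
LMG0076
LMG0077
LMG0078
LMG0079
LMG0080
LMG0081
LMG0082
LMG0083
LMG0084
LMG0085
LMG0086
LMG0087
LMG0088
LMG0089
LMG0090
LMG0091
LMG0092
LMG0093
LMG0094
LMG0095
LMG0096
LMG0097
LMG0098
LMG0099
LMG0100
LMG0101
LMG0102
LMG0103
LMG0104
LMG0105
LMG0106
LMG0107
LMG0108
LMG0109
LMG0110
LMG0111
LMG0112
LMG0113
LMG0114
LMG0115
LMG0116
LMG0117
LMG0118
LMG0119
LMG0120
LMG0121
LMG0122
LMG0123
LMG0124
LMG0125
LMG0126
LMG0127
LMG0128
LMG0129
LMG0130
LMG0131
LMG0132
LMG0133
LMG0134
LMG0135
LMG0136
LMG0137
LMG0138
LMG0139
LMG0140
LMG0141
LMG0142
LMG0143
LMG0144
LMG0145
LMG0146
LMG0147
LMG0148
LMG0149
LMG0150
LMG0151
LMG0152
LMG0153
LMG0154
LMG0155
LMG0156
LMG0157
LMG0158
LMG0159
LMG0160
LMG0161
LMG0162
LMG0163
LMG0164
LMG0165
LMG0166
LMG0167
LMG0168
LMG0169
LMG0170
LMG0171
LMG0172
LMG0173
LMG0174
LMG0175
LMG0176
LMG0177
LMG0178
LMG0179
LMG0180
LMG0181
LMG0182
LMG0183
LMG0184
LMG0185
LMG0186
LMG0187
LMG0188
LMG0189
LMG0190
LMG0191
LMG0192
LMG0193
LMG0194
LMG0195
LMG0196
LMG0197
LMG0198
LMG0199
LMG0200
LMG0201
LMG0202
LMG0203
LMG0204
LMG0205
LMG0206
LMG0207
LMG0208
LMG0209
LMG0210
LMG0211
LMG0212
LMG0213
LMG0214
LMG0215
LMG0216
LMG0217
LMG0218
LMG0219
LMG0220
LMG0221
LMG0222
LMG0223
LMG0224
LMG0225
LMG0226
LMG0227
LMG0228
LMG0229
LMG0230
LMG0231
LMG0232
LMG0233
LMG0234
LMG0235
LMG0236
LMG0237
LMG0238
LMG0239
LMG0240
LMG0241
LMG0242
LMG0243
LMG0244
LMG0245
LMG0246
LMG0247
LMG0248
LMG0249
LMG0250
LMG0251
LMG0252
LMG0253
LMG0254
LMG0255
LMG0256
LMG0257
LMG0258
LMG0259
LMG0260
LMG0261
LMG0262
LMG0263
LMG0264
LMG0265
LMG0266
LMG0267
LMG0268
LMG0269
LMG0270
LMG0271
LMG0272
LMG0273
LMG0274
LMG0275
LMG0276
LMG0277
LMG0278
LMG0279
LMG0280
LMG0281
LMG0282
LMG0283
LMG0284
LMG0285
LMG0286
LMG0287
LMG0288
LMG0289
LMG0290
LMG0291
LMG0292
LMG0293
LMG0294
LMG0295
LMG0296
LMG0297
LMG0298
LMG0299
LMG0300
LMG0301
LMG0302
LMG0303
LMG0304
LMG0305
LMG0306
LMG0307
LMG0308
LMG0309
LMG0310
LMG0311
LMG0312
LMG0313
LMG0314
LMG0315
LMG0316
LMG0317
LMG0318
LMG0319
LMG0320
LMG0321
LMG0322
LMG0323
LMG0324
LMG0325
LMG0326
LMG0327
LMG0328
LMG0329
LMG0330
LMG0331
LMG0332
LMG0333
LMG0334
LMG0335
LMG0336
LMG0337
LMG0338
LMG0339
LMG0340
LMG0341
LMG0342
LMG0343
LMG0344
LMG0345
LMG0346
LMG0347
LMG0348
LMG0349
LMG0350
LMG0351
LMG0352
LMG0353
LMG0354
LMG0355
LMG0356
LMG0357
LMG0358
LMG0359
LMG0360
LMG0361
LMG0362
LMG0363
LMG0364
LMG0365
LMG0366
LMG0367
LMG0368
LMG0369
LMG0370
LMG0371
LMG0372
LMG0373
LMG0374
LMG0375
LMG0376
LMG0377
LMG0378
LMG0379
LMG0380
LMG0381
LMG0382
LMG0383
LMG0384
LMG0385
LMG0386
LMG0387
LMG0388
LMG0389
LMG0390
LMG0391
LMG0392
LMG0393
LMG0394
LMG0395
LMG0396
LMG0397
LMG0398
LMG0399
LMG0400
LMG0401
LMG0402
LMG0403
LMG0404
LMG0405
LMG0406
LMG0407
LMG0408
LMG0409
LMG0410
LMG0411
LMG0412
LMG0413
LMG0414
LMG0415
LMG0416
LMG0417
LMG0418
LMG0419
LMG0420
LMG0421
LMG0422
LMG0423
LMG0424
LMG0425
LMG0426
LMG0427
LMG0428
LMG0429
LMG0430
LMG0431
LMG0432
LMG0433
LMG0434
LMG0435
LMG0436
LMG0437
LMG0438
LMG0439
LMG0440
LMG0441
LMG0442
LMG0443
LMG0444
LMG0445
LMG0446
LMG0447
LMG0448
LMG0449
LMG0450
LMG0451
LMG0452
LMG0453
LMG0454
LMG0455
LMG0456
LMG0457
LMG0458
LMG0459
LMG0460
LMG0461
LMG0462
LMG0463
LMG0464
LMG0465
LMG0466
LMG0467
LMG0468
LMG0469
LMG0470
LMG0471
LMG0472
LMG0473
LMG0474
LMG0475
LMG0476
LMG0477
LMG0478
LMG0479
LMG0480
LMG0481
LMG0482
LMG0483
LMG0484
LMG0485
LMG0486
LMG0487
LMG0488
LMG0489
LMG0490
LMG0491
LMG0492
LMG0493
LMG0494
LMG0495
LMG0496
LMG0497
LMG0498
LMG0499
LMG0500
LMG0501
LMG0502
LMG0503
LMG0504
LMG0505
LMG0506
LMG0507
LMG0508
LMG0509
LMG0510
LMG0511
LMG0512
LMG0513
LMG0514
LMG0515
LMG0516
LMG0517
LMG0518
LMG0519
LMG0520
LMG0521
LMG0522
LMG0523
LMG0524
LMG0525
LMG0526
LMG0527
LMG0528
LMG0529
LMG0530
LMG0531
LMG0532
LMG0533
LMG0534
LMG0535
LMG0536
LMG0537
LMG0538
LMG0539
LMG0540
LMG0541
LMG0542
LMG0543
LMG0544
LMG0545
LMG0546
LMG0547
LMG0548
LMG0549
LMG0550
LMG0551
LMG0552
LMG0553
LMG0554
LMG0555
LMG0556
LMG0557
LMG0558
LMG0559
LMG0560
LMG0561
LMG0562
LMG0563
LMG0564
LMG0565
LMG0566
LMG0567
LMG0568
LMG0569
LMG0570
LMG0571
LMG0572
LMG0573
LMG0574
LMG0575
LMG0576
LMG0577
LMG0578
LMG0579
LMG0580
LMG0581
LMG0582
LMG0583
LMG0584
LMG0585
LMG0586
LMG0587
LMG0588
LMG0589
LMG0590
LMG0591
LMG0592
LMG0593
LMG0594
LMG0595
LMG0596
LMG0597
LMG0598
LMG0599
LMG0600
LMG0601
LMG0602
LMG0603
LMG0604
LMG0605
LMG0606
LMG0607
LMG0608
LMG0609
LMG0610
LMG0611
LMG0612
LMG0613
LMG0614
LMG0615
LMG0616
LMG0617
LMG0618
LMG0619
LMG0620
LMG0621
LMG0622
LMG0623
LMG0624
LMG0625
LMG0626
LMG0627
LMG0628
LMG0629
LMG0630
LMG0631
LMG0632
LMG0633
LMG0634
LMG0635
LMG0636
LMG0637
LMG0638
LMG0639
LMG0640
LMG0641
LMG0642
LMG0643
LMG0644
LMG0645
LMG0646
LMG0647
LMG0648
LMG0649
LMG0650
LMG0651
LMG0652
LMG0653
LMG0654
LMG0655
LMG0656
LMG0657
LMG0658
LMG0659
LMG0660
LMG0661
LMG0662
LMG0663
LMG0664
LMG0665
LMG0666
LMG0667
LMG0668
LMG0669
LMG0670
LMG0671
LMG0672
LMG0673
LMG0674
LMG0675
LMG0676
LMG0677
LMG0678
LMG0679
LMG0680
LMG0681
LMG0682
LMG0683
LMG0684
LMG0685
LMG0686
LMG0687
LMG0688
LMG0689
LMG0690
LMG0691
LMG0692
LMG0693
LMG0694
LMG0695
LMG0696
LMG0697
LMG0698
LMG0699
LMG0700
LMG0701
LMG0702
LMG0703
LMG0704
LMG0705
LMG0706
LMG0707
LMG0708
LMG0709
LMG0710
LMG0711
LMG0712
LMG0713
LMG0714
LMG0715
LMG0716
LMG0717
LMG0718
LMG0719
LMG0720
LMG0721
LMG0722
LMG0723
LMG0724
LMG0725
LMG0726
LMG0727
LMG0728
LMG0729
LMG0730
LMG0731
LMG0732
LMG0733
LMG0734
LMG0735
LMG0736
LMG0737
LMG0738
LMG0739
LMG0740
LMG0741
LMG0742
LMG0743
LMG0744
LMG0745
LMG0746
LMG0747
LMG0748
LMG0749
LMG0750
LMG0751
LMG0752
LMG0753
LMG0754
LMG0755
LMG0756
LMG0757
LMG0758
LMG0759
LMG0760
LMG0761
LMG0762
LMG0763
LMG0764
LMG0765
LMG0766
LMG0767
LMG0768
LMG0769
LMG0770
LMG0771
LMG0772
LMG0773
LMG0774
LMG0775
LMG0776
LMG0777
LMG0778
LMG0779
LMG0780
LMG0781
LMG0782
LMG0783
LMG0784
LMG0785
LMG0786
LMG0787
LMG0788
LMG0789
LMG0790
LMG0791
LMG0792
LMG0793
LMG0794
LMG0795
LMG0796
LMG0797
LMG0798
LMG0799
LMG0800
LMG0801
LMG0802
LMG0803
LMG0804
LMG0805
LMG0806
LMG0807
LMG0808
LMG0809
LMG0810
LMG0811
LMG0812
LMG0813
LMG0814
LMG0815
LMG0816
LMG0817
LMG0818
LMG0819
LMG0820
LMG0821
LMG0822
LMG0823
LMG0824
LMG0825
LMG0826
LMG0827
LMG0828
LMG0829
LMG0830
LMG0831
LMG0832
LMG0833
LMG0834
LMG0835
LMG0836
LMG0837
LMG0838
LMG0839
LMG0840
LMG0841
LMG0842
LMG0843
LMG0844
LMG0845
LMG0846
LMG0847
LMG0848
LMG0849
LMG0850
LMG0851
LMG0852
LMG0853
LMG0854
LMG0855
LMG0856
LMG0857
LMG0858
LMG0859
LMG0860
LMG0861
LMG0862
LMG0863
LMG0864
LMG0865
LMG0866
LMG0867
LMG0868
LMG0869
LMG0870
LMG0871
LMG0872
LMG0873
LMG0874
LMG0875
LMG0876
LMG0877
LMG0878
LMG0879
LMG0880
LMG0881
LMG0882
LMG0883
LMG0884
LMG0885
LMG0886
LMG0887
LMG0888
LMG0889
LMG0890
LMG0891
LMG0892
LMG0893
LMG0894
LMG0895
LMG0896
LMG0897
LMG0898
LMG0899
LMG0900
LMG0901
LMG0902
LMG0903
LMG0904
LMG0905
LMG0906
LMG0907
LMG0908
LMG0909
LMG0910
LMG0911
LMG0912
LMG0913
LMG0914
LMG0915
LMG0916
LMG0917
LMG0918
LMG0919
LMG0920
LMG0921
LMG0922
LMG0923
LMG0924
LMG0925
LMG0926
LMG0927
LMG0928
LMG0929
LMG0930
LMG0931
LMG0932
LMG0933
LMG0934
LMG0935
LMG0936
LMG0937
LMG0938
LMG0939
LMG0940
LMG0941
LMG0942
LMG0943
LMG0944
LMG0945
LMG0946
LMG0947
LMG0948
LMG0949
LMG0950
LMG0951
LMG0952
LMG0953
LMG0954
LMG0955
LMG0956
LMG0957
LMG0958
LMG0959
LMG0960
LMG0961
LMG0962
LMG0963
LMG0964
LMG0965
LMG0966
LMG0967
LMG0968
LMG0969
LMG0970
LMG0971
LMG0972
LMG0973
LMG0974
LMG0975
LMG0976
LMG0977
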
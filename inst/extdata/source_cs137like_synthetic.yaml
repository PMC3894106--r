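name: Cs-137-like synthetic source model (fixture; not a published dataset)
synthetic: yes
active_length_cm: 1.48
physical_diameter_cm: 0.3
radial_dose:
  type: poly
  coefficients:
  - 1.01
  - -0.008
  - -0.002
  - -0.0001
  - 0.0
  - 0.0
  r_range:
  - 0.01
  - 7.5
anisotropy:
  theta_deg:
  - 2.0
  - 5.0
  - 10.0
  - 15.0
  - 20.0
  - 30.0
  - 40.0
  - 50.0
  - 60.0
  - 70.0
  - 80.0
  - 85.0
  - 90.0
  - 95.0
  - 100.0
  - 110.0
  - 120.0
  - 130.0
  - 140.0
  - 150.0
  - 160.0
  - 165.0
  - 170.0
  - 172.0
  - 174.0
  - 176.0
  - 178.0
  r_cm:
  - 0.25
  - 0.5
  - 0.75
  - 1.0
  - 1.5
  - 2.0
  - 3.0
  - 4.0
  - 5.0
  - 7.0
  values:
  - - 0.88011
    - 0.880685
    - 0.882734
    - 0.886131
    - 0.890842
    - 0.903971
    - 0.921344
    - 0.941563
    - 0.9625
    - 0.981345
    - 0.994887
    - 0.998672
    - 1.0
    - 0.998593
    - 0.994258
    - 0.976543
    - 0.9475
    - 0.909693
    - 0.8674
    - 0.826029
    - 0.79127
    - 0.777984
    - 0.768121
    - 0.765221
    - 0.762947
    - 0.761313
    - 0.760329
  - - 0.920061
    - 0.920381
    - 0.921528
    - 0.923451
    - 0.926163
    - 0.933971
    - 0.944817
    - 0.95809
    - 0.9725
    - 0.986024
    - 0.996093
    - 0.998976
    - 1.0
    - 0.998897
    - 0.995464
    - 0.981223
    - 0.9575
    - 0.92622
    - 0.890873
    - 0.856029
    - 0.826591
    - 0.815305
    - 0.806915
    - 0.804446
    - 0.80251
    - 0.801119
    - 0.80028
  - - 0.933378
    - 0.933613
    - 0.93446
    - 0.935892
    - 0.937937
    - 0.943971
    - 0.952641
    - 0.963599
    - 0.975833
    - 0.987583
    - 0.996495
    - 0.999078
    - 1.0
    - 0.998998
    - 0.995866
    - 0.982782
    - 0.960833
    - 0.931729
    - 0.898697
    - 0.866029
    - 0.838364
    - 0.827745
    - 0.819846
    - 0.817522
    - 0.815698
    - 0.814387
    - 0.813597
  - - 0.940037
    - 0.940229
    - 0.940925
    - 0.942112
    - 0.943824
    - 0.948971
    - 0.956553
    - 0.966354
    - 0.9775
    - 0.988363
    - 0.996696
    - 0.999128
    - 1.0
    - 0.999049
    - 0.996067
    - 0.983562
    - 0.9625
    - 0.934484
    - 0.902609
    - 0.871029
    - 0.844251
    - 0.833965
    - 0.826312
    - 0.824059
    - 0.822292
    - 0.821021
    - 0.820256
  - - 0.946695
    - 0.946845
    - 0.947391
    - 0.948332
    - 0.94971
    - 0.953971
    - 0.960465
    - 0.969108
    - 0.979167
    - 0.989143
    - 0.996897
    - 0.999179
    - 1.0
    - 0.999099
    - 0.996268
    - 0.984342
    - 0.964167
    - 0.937238
    - 0.906521
    - 0.876029
    - 0.850138
    - 0.840185
    - 0.832777
    - 0.830597
    - 0.828886
    - 0.827656
    - 0.826914
  - - 0.950024
    - 0.950153
    - 0.950624
    - 0.951442
    - 0.952654
    - 0.956471
    - 0.962421
    - 0.970486
    - 0.98
    - 0.989533
    - 0.996997
    - 0.999204
    - 1.0
    - 0.999125
    - 0.996369
    - 0.984732
    - 0.965
    - 0.938616
    - 0.908477
    - 0.878529
    - 0.853081
    - 0.843295
    - 0.83601
    - 0.833865
    - 0.832183
    - 0.830973
    - 0.830244
  - - 0.953354
    - 0.953461
    - 0.953856
    - 0.954552
    - 0.955597
    - 0.958971
    - 0.964377
    - 0.971863
    - 0.980833
    - 0.989923
    - 0.997098
    - 0.999229
    - 1.0
    - 0.99915
    - 0.996469
    - 0.985122
    - 0.965833
    - 0.939993
    - 0.910433
    - 0.881029
    - 0.856025
    - 0.846405
    - 0.839243
    - 0.837134
    - 0.835479
    - 0.83429
    - 0.833573
  - - 0.955018
    - 0.955115
    - 0.955473
    - 0.956107
    - 0.957069
    - 0.960221
    - 0.965355
    - 0.972552
    - 0.98125
    - 0.990118
    - 0.997148
    - 0.999242
    - 1.0
    - 0.999163
    - 0.99652
    - 0.985317
    - 0.96625
    - 0.940681
    - 0.911411
    - 0.882279
    - 0.857496
    - 0.84796
    - 0.840859
    - 0.838769
    - 0.837128
    - 0.835948
    - 0.835237
  - - 0.956017
    - 0.956108
    - 0.956443
    - 0.95704
    - 0.957952
    - 0.960971
    - 0.965942
    - 0.972965
    - 0.9815
    - 0.990235
    - 0.997178
    - 0.99925
    - 1.0
    - 0.99917
    - 0.99655
    - 0.985434
    - 0.9665
    - 0.941095
    - 0.911998
    - 0.883029
    - 0.85838
    - 0.848893
    - 0.841829
    - 0.839749
    - 0.838117
    - 0.836943
    - 0.836236
  - - 0.957159
    - 0.957242
    - 0.957551
    - 0.958106
    - 0.958961
    - 0.961828
    - 0.966613
    - 0.973437
    - 0.981786
    - 0.990369
    - 0.997213
    - 0.999258
    - 1.0
    - 0.999179
    - 0.996584
    - 0.985567
    - 0.966786
    - 0.941567
    - 0.912669
    - 0.883886
    - 0.859389
    - 0.84996
    - 0.842938
    - 0.84087
    - 0.839247
    - 0.838081
    - 0.837378
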
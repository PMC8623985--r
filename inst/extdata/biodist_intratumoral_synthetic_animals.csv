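animal_id,organ,time_h,pct_id_per_g
m01,blood,4,1.03804
m02,blood,4,3.96601
m03,blood,4,6.89399
m04,blood,4,9.82196
m01,blood,24,0.12514
m02,blood,24,0.14838
m03,blood,24,0.17162
m04,blood,24,0.19486
m01,blood,48,0.12867
m02,blood,48,0.18289
m03,blood,48,0.23711
m04,blood,48,0.29133
m01,blood,72,0.12676
m02,blood,72,0.14225
m03,blood,72,0.15775
m04,blood,72,0.17324
m01,heart,4,0.38477
m02,heart,4,0.88826
m03,heart,4,1.39174
m04,heart,4,1.89523
m01,heart,24,0.11895
m02,heart,24,0.21965
m03,heart,24,0.32035
m04,heart,24,0.42105
m01,heart,48,0.17191
m02,heart,48,0.21064
m03,heart,48,0.24936
m04,heart,48,0.28809
m01,heart,72,0.06543
m02,heart,72,0.13514
m03,heart,72,0.20486
m04,heart,72,0.27457
m01,lung,4,1.4862
m02,lung,4,2.22207
m03,lung,4,2.95793
m04,lung,4,3.6938
m01,lung,24,0.29877
m02,lung,24,0.63959
m03,lung,24,0.98041
m04,lung,24,1.32123
m01,lung,48,0.23657
m02,lung,48,0.49219
m03,lung,48,0.74781
m04,lung,48,1.00343
m01,lung,72,0.22629
m02,lung,72,0.43543
m03,lung,72,0.64457
m04,lung,72,0.85371
m01,liver,4,3.68147
m02,liver,4,7.16716
m03,liver,4,10.65284
m04,liver,4,14.13853
m01,liver,24,10.16254
m02,liver,24,15.17418
m03,liver,24,20.18582
m04,liver,24,25.19746
m01,liver,48,5.7708
m02,liver,48,8.87693
m03,liver,48,11.98307
m04,liver,48,15.0892
m01,liver,72,2.01729
m02,liver,72,5.90576
m03,liver,72,9.79424
m04,liver,72,13.68271
m01,stomach,4,0.47381
m02,stomach,4,0.55127
m03,stomach,4,0.62873
m04,stomach,4,0.70619
m01,stomach,24,0.27867
m02,stomach,24,0.33289
m03,stomach,24,0.38711
m04,stomach,24,0.44133
m01,stomach,48,0.27381
m02,stomach,48,0.35127
m03,stomach,48,0.42873
m04,stomach,48,0.50619
m01,stomach,72,0.28676
m02,stomach,72,0.30225
m03,stomach,72,0.31775
m04,stomach,72,0.33324
m01,small intestine,4,0.51953
m02,small intestine,4,0.71318
m03,small intestine,4,0.90682
m04,small intestine,4,1.10047
m01,small intestine,24,0.27305
m02,small intestine,24,0.49768
m03,small intestine,24,0.72232
m04,small intestine,24,0.94695
m01,small intestine,48,0.29848
m02,small intestine,48,0.59283
m03,small intestine,48,0.88717
m04,small intestine,48,1.18152
m01,small intestine,72,0.20514
m02,small intestine,72,0.22838
m03,small intestine,72,0.25162
m04,small intestine,72,0.27486
m01,large intestine,4,0.31248
m02,large intestine,4,0.44416
m03,large intestine,4,0.57584
m04,large intestine,4,0.70752
m01,large intestine,24,0.13029
m02,large intestine,24,0.17676
m03,large intestine,24,0.22324
m04,large intestine,24,0.26971
m01,large intestine,48,0.14543
m02,large intestine,48,0.21514
m03,large intestine,48,0.28486
m04,large intestine,48,0.35457
m01,large intestine,72,0.06867
m02,large intestine,72,0.12289
m03,large intestine,72,0.17711
m04,large intestine,72,0.23133
m01,spleen,4,4.43306
m02,spleen,4,5.47102
m03,spleen,4,6.50898
m04,spleen,4,7.54694
m01,spleen,24,5.30641
m02,spleen,24,7.4288
m03,spleen,24,9.5512
m04,spleen,24,11.67359
m01,spleen,48,1.63155
m02,spleen,48,3.77718
m03,spleen,48,5.92282
m04,spleen,48,8.06845
m01,spleen,72,0.0783999999999998
m02,spleen,72,1.7128
m03,spleen,72,3.3472
m04,spleen,72,4.9816
m01,pancreas,4,0.35953
m02,pancreas,4,0.55318
m03,pancreas,4,0.74682
m04,pancreas,4,0.94047
m01,pancreas,24,0.06191
m02,pancreas,24,0.10064
m03,pancreas,24,0.13936
m04,pancreas,24,0.17809
m01,pancreas,48,0.08352
m02,pancreas,48,0.11451
m03,pancreas,48,0.14549
m04,pancreas,48,0.17648
m01,pancreas,72,0.10514
m02,pancreas,72,0.12838
m03,pancreas,72,0.15162
m04,pancreas,72,0.17486
m01,kidney,4,6.89021
m02,kidney,4,8.27674
m03,kidney,4,9.66326
m04,kidney,4,11.04979
m01,kidney,24,4.63488
m02,kidney,24,6.23829
m03,kidney,24,7.84171
m04,kidney,24,9.44512
m01,kidney,48,3.3921
m02,kidney,48,4.00403
m03,kidney,48,4.61597
m04,kidney,48,5.2279
m01,kidney,72,2.41744
m02,kidney,72,3.62581
m03,kidney,72,4.83419
m04,kidney,72,6.04256
m01,bone,4,0.54543
m02,bone,4,0.61514
m03,bone,4,0.68486
m04,bone,4,0.75457
m01,bone,24,0.81029
m02,bone,24,0.85676
m03,bone,24,0.90324
m04,bone,24,0.94971
m01,bone,48,1.26362
m02,bone,48,1.58121
m03,bone,48,1.89879
m04,bone,48,2.21638
m01,bone,72,1.16591
m02,bone,72,1.8553
m03,bone,72,2.5447
m04,bone,72,3.23409
m01,muscle,4,0.11733
m02,muscle,4,0.22578
m03,muscle,4,0.33422
m04,muscle,4,0.44267
m01,muscle,24,0
m02,muscle,24,0.04667
m03,muscle,24,0.09333
m04,muscle,24,0.14
m01,muscle,48,0.04191
m02,muscle,48,0.08064
m03,muscle,48,0.11936
m04,muscle,48,0.15809
m01,muscle,72,0
m02,muscle,72,0.02667
m03,muscle,72,0.05333
m04,muscle,72,0.08
m01,tumor,4,93.41674
m02,tumor,4,114.53225
m03,tumor,4,135.64775
m04,tumor,4,156.76326
m01,tumor,24,60.45155
m02,tumor,24,100.20385
m03,tumor,24,139.95615
m04,tumor,24,179.70845
m01,tumor,48,27.66102
m02,tumor,48,32.96701
m03,tumor,48,38.27299
m04,tumor,48,43.57898
m01,tumor,72,44.23233
m02,tumor,72,55.70411
m03,tumor,72,67.17589
m04,tumor,72,78.64767
m01,bone marrow,4,0.55144
m02,bone marrow,4,1.59715
m03,bone marrow,4,2.64285
m04,bone marrow,4,3.68856
m01,bone marrow,24,0
m02,bone marrow,24,0.36667
m03,bone marrow,24,0.73333
m04,bone marrow,24,1.1
m01,bone marrow,48,1.15077
m02,bone marrow,48,1.81692
m03,bone marrow,48,2.48308
m04,bone marrow,48,3.14923
m01,bone marrow,72,0
m02,bone marrow,72,0
m03,bone marrow,72,0
m04,bone marrow,72,0
m01,brain,4,0.06705
m02,brain,4,0.12902
m03,brain,4,0.19098
m04,brain,4,0.25295
m01,brain,24,0
m02,brain,24,0.01333
m03,brain,24,0.02667
m04,brain,24,0.04
m01,brain,48,0.00838
m02,brain,48,0.01613
m03,brain,48,0.02387
m04,brain,48,0.03162
m01,brain,72,0
m02,brain,72,0.02
m03,brain,72,0.04
m04,brain,72,0.06
m01,urine,4,89.02355
m02,urine,4,151.82785
m03,urine,4,214.63215
m04,urine,4,277.43645
m01,urine,24,0
m02,urine,24,7.60667
m03,urine,24,15.21333
m04,urine,24,22.82
m01,urine,48,0.76192
m02,urine,48,1.61397
m03,urine,48,2.46603
m04,urine,48,3.31808
m01,urine,72,0
m02,urine,72,1.66
m03,urine,72,3.32
m04,urine,72,4.98
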
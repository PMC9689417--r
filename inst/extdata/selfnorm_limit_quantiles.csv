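"statistic","prob","quantile"
"sum",0.01,0.622146486697522
"sum",0.02,0.644448702660913
"sum",0.03,0.66155780943868
"sum",0.04,0.676319472604141
"sum",0.05,0.689837167713935
"sum",0.06,0.70213177159272
"sum",0.07,0.714543044521857
"sum",0.08,0.726949602711058
"sum",0.09,0.73909755814064
"sum",0.1,0.750918861507967
"sum",0.11,0.763310808495858
"sum",0.12,0.775557146182777
"sum",0.13,0.787401393533633
"sum",0.14,0.800319000480017
"sum",0.15,0.812447849649415
"sum",0.16,0.82532920304768
"sum",0.17,0.838103369592505
"sum",0.18,0.851611242082768
"sum",0.19,0.866309950992916
"sum",0.2,0.880763914993674
"sum",0.21,0.895812494583951
"sum",0.22,0.910507347220322
"sum",0.23,0.927237297821389
"sum",0.24,0.944573315280915
"sum",0.25,0.963550276203177
"sum",0.26,0.982251561798376
"sum",0.27,1.00197459057978
"sum",0.28,1.024067723777
"sum",0.29,1.0461714761605
"sum",0.3,1.07012558783639
"sum",0.31,1.09499067792868
"sum",0.32,1.11999364797353
"sum",0.33,1.14767051590075
"sum",0.34,1.17543595799957
"sum",0.35,1.20467602348323
"sum",0.36,1.23500425280211
"sum",0.37,1.26370752973222
"sum",0.38,1.29612715660678
"sum",0.39,1.32942157452172
"sum",0.4,1.36538849182861
"sum",0.41,1.39878558186144
"sum",0.42,1.4339787145994
"sum",0.43,1.47250829434651
"sum",0.44,1.51076904944768
"sum",0.45,1.55107825837594
"sum",0.46,1.59238129787927
"sum",0.47,1.63555740644537
"sum",0.48,1.67886941126879
"sum",0.49,1.72434998205107
"sum",0.5,1.77096487593687
"sum",0.51,1.81862744695253
"sum",0.52,1.870552779762
"sum",0.53,1.92384896351852
"sum",0.54,1.97757449883056
"sum",0.55,2.03310360092952
"sum",0.56,2.08622028357797
"sum",0.57,2.14026665862256
"sum",0.58,2.19733435180418
"sum",0.59,2.25780308283036
"sum",0.6,2.32098820266997
"sum",0.61,2.38510161550489
"sum",0.62,2.45217407199373
"sum",0.63,2.51884390217014
"sum",0.64,2.58940098351746
"sum",0.65,2.65930978136907
"sum",0.66,2.73548027225602
"sum",0.67,2.80880453303288
"sum",0.68,2.88919308515166
"sum",0.69,2.9657673684254
"sum",0.7,3.0484327016124
"sum",0.71,3.13569565371659
"sum",0.72,3.2209824728097
"sum",0.73,3.31199356064857
"sum",0.74,3.40382775730166
"sum",0.75,3.49843936028541
"sum",0.76,3.60069491409897
"sum",0.77,3.7082711479366
"sum",0.78,3.81265984707727
"sum",0.79,3.9280576486541
"sum",0.8,4.04467596197098
"sum",0.81,4.15808462612346
"sum",0.82,4.29232994660406
"sum",0.83,4.4249163899809
"sum",0.84,4.5622854336307
"sum",0.85,4.70158759834935
"sum",0.86,4.86261069269531
"sum",0.87,5.02377073858363
"sum",0.88,5.20125945248612
"sum",0.89,5.39534512446889
"sum",0.9,5.60808554188942
"sum",0.91,5.84074818223471
"sum",0.92,6.08940767071334
"sum",0.93,6.37362870228481
"sum",0.94,6.70437216701606
"sum",0.95,7.07111699549651
"sum",0.96,7.55680855767979
"sum",0.97,8.14611827852188
"sum",0.98,8.96883284087989
"sum",0.99,10.3813915803428
"sum",0.991,10.5817237653374
"sum",0.992,10.835521600359
"sum",0.993,11.0895686536926
"sum",0.994,11.3687050772448
"sum",0.995,11.7759006733999
"sum",0.996,12.2683147769763
"sum",0.997,12.9097161648652
"sum",0.998,13.686805339683
"sum",0.999,15.2283834431526
"max",0.01,2.32817174765178
"max",0.02,2.44340941340381
"max",0.03,2.53047532463459
"max",0.04,2.6033081536319
"max",0.05,2.66927577242896
"max",0.06,2.73519175023412
"max",0.07,2.80240279228223
"max",0.08,2.86517604502539
"max",0.09,2.92826941165487
"max",0.1,2.99787547762156
"max",0.11,3.06683205947461
"max",0.12,3.13611419015107
"max",0.13,3.20702940049357
"max",0.14,3.27892140778674
"max",0.15,3.34932468591258
"max",0.16,3.42767186278649
"max",0.17,3.50738133690679
"max",0.18,3.58605310984062
"max",0.19,3.66432446936718
"max",0.2,3.74499678922624
"max",0.21,3.83289927923673
"max",0.22,3.92259741280953
"max",0.23,4.0104290105448
"max",0.24,4.09549859120408
"max",0.25,4.18245922804837
"max",0.26,4.27802743758793
"max",0.27,4.37897887509173
"max",0.28,4.47774004603601
"max",0.29,4.58035446016971
"max",0.3,4.68840756564532
"max",0.31,4.79834828531449
"max",0.32,4.91690098897842
"max",0.33,5.02747509347585
"max",0.34,5.14490367873395
"max",0.35,5.27111553510052
"max",0.36,5.3965748414378
"max",0.37,5.52606001337722
"max",0.38,5.65895176263682
"max",0.39,5.80201527899663
"max",0.4,5.94720324572849
"max",0.41,6.09692879888021
"max",0.42,6.25264576745458
"max",0.43,6.4101468083775
"max",0.44,6.5756947441792
"max",0.45,6.74839230478561
"max",0.46,6.92347658021873
"max",0.47,7.10366957831072
"max",0.48,7.28914633960359
"max",0.49,7.48556631993273
"max",0.5,7.68756211533401
"max",0.51,7.90334074223769
"max",0.52,8.11527200844808
"max",0.53,8.32459534609114
"max",0.54,8.55216254606302
"max",0.55,8.79904209698935
"max",0.56,9.04894101392614
"max",0.57,9.29576371539097
"max",0.58,9.55440567981704
"max",0.59,9.82902260427425
"max",0.6,10.1062053819285
"max",0.61,10.4001332120984
"max",0.62,10.7217297832717
"max",0.63,11.0403832175183
"max",0.64,11.3418745862899
"max",0.65,11.6708359881503
"max",0.66,12.0166814550385
"max",0.67,12.3782127903845
"max",0.68,12.7717576209626
"max",0.69,13.1797075633243
"max",0.7,13.6053106534654
"max",0.71,14.0568915976959
"max",0.72,14.4908719234384
"max",0.73,14.9708471341925
"max",0.74,15.4531676632869
"max",0.75,15.96458452113
"max",0.76,16.5023847268273
"max",0.77,17.081764461549
"max",0.78,17.7150534910221
"max",0.79,18.3445110095641
"max",0.8,19.0369639826175
"max",0.81,19.7615612838067
"max",0.82,20.531375245184
"max",0.83,21.3696368654982
"max",0.84,22.282872830469
"max",0.85,23.1940060746856
"max",0.86,24.2006585132062
"max",0.87,25.3472457730522
"max",0.88,26.5747711923321
"max",0.89,27.9464511229833
"max",0.9,29.458001860585
"max",0.91,31.1255653103328
"max",0.92,33.0503314237593
"max",0.93,35.163745038009
"max",0.94,37.8755906800409
"max",0.95,41.0205977322023
"max",0.96,44.8653276665149
"max",0.97,50.1303102206016
"max",0.98,57.61490735183
"max",0.99,71.816961359998
"max",0.991,74.253714225885
"max",0.992,77.2973082948178
"max",0.993,80.5706740562805
"max",0.994,83.6871337273633
"max",0.995,87.9760140482651
"max",0.996,93.0943574466014
"max",0.997,99.6551213461349
"max",0.998,110.506307244225
"max",0.999,129.838650618542
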
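# material=aluminum
r_outer_cm,thickness_cm
0.14599999999999999,0.59846068239963468
0.29199999999999998,0.59538731725987992
0.43799999999999994,0.58019327098299989
0.58399999999999996,0.56556066104446223
0.72999999999999998,0.53970298749436629
0.87599999999999989,0.51559715520595162
1.022,0.48169335667263558
1.1679999999999999,0.45113761636658467
1.3140000000000001,0.41247665029500225
1.46,0.3788799677901884
1.6059999999999999,0.3388486272636323
1.7519999999999998,0.305445006329363
1.8979999999999999,0.26701217883185424
2.044,0.23641627882685823
2.1899999999999999,0.20177940193705579
2.3359999999999999,0.1757354164360681
2.4819999999999998,0.14617534432499413
2.6280000000000001,0.12551397486099564
2.7739999999999996,0.10144387930487492
2.9199999999999999,0.08620822887548743
3.0659999999999998,0.067358544439832357
3.2119999999999997,0.057028930136931194
3.3580000000000001,0.042693217247780316
3.5039999999999996,0.036436966347273864
3.6499999999999999,0.025711197909534307
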
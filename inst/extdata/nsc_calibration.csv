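alpha,beta,n_sc_star
0.1,0.5,2.76940653818856
0.1,0.55,3.10699717789096
0.1,0.6,3.46925384864228
0.1,0.65,3.8707791857565
0.1,0.7,4.33327798864415
0.1,0.75,4.86459716845316
0.1,0.8,5.46057256484328
0.1,0.85,6.18773544129467
0.1,0.9,7.07381018454586
0.1,0.95,8.50668858407338
0.05,0.5,3.64346896137261
0.05,0.55,4.03841962683525
0.05,0.6,4.48020677977234
0.05,0.65,4.95378940798644
0.05,0.7,5.46260593599857
0.05,0.75,6.03734124190286
0.05,0.8,6.64798545027018
0.05,0.85,7.33209578538391
0.05,0.9,8.27441596058063
0.05,0.95,9.88647224008441
0.01,0.5,5.77136335639508
0.01,0.55,6.24528674240383
0.01,0.6,6.68424051600127
0.01,0.65,7.12883864683304
0.01,0.7,7.62785282533374
0.01,0.75,8.21117514256466
0.01,0.8,8.92317481437181
0.01,0.85,9.79017345148278
0.01,0.9,11.0415932706464
0.01,0.95,12.6166103551898
0.005,0.5,6.57656414630066
0.005,0.55,6.98906032886163
0.005,0.6,7.42753244267814
0.005,0.65,7.92207731228893
0.005,0.7,8.4891169292499
0.005,0.75,9.13514447481929
0.005,0.8,9.91510214156864
0.005,0.85,10.8979958494725
0.005,0.9,11.9685638254339
0.005,0.95,13.9749946351122
0.001,0.5,8.21269200020153
0.001,0.55,8.73819108009992
0.001,0.6,9.30303478456048
0.001,0.65,9.93328325823918
0.001,0.7,10.6190984678513
0.001,0.75,11.3156732435061
0.001,0.8,12.0462619663172
0.001,0.85,12.9902277262904
0.001,0.9,14.4337258428681
0.001,0.95,16.1974195482101
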
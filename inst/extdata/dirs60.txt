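-0.07871865 0.50326217 0.86054085
0.64867473 -0.62487231 0.43446023
-0.21241271 0.21833585 0.95247588
-0.88425339 0.46696314 0.00643198
-0.69144383 -0.45098382 0.56437490
0.41936913 0.89170159 0.17028742
0.70422505 0.70899423 0.03733983
0.12225242 -0.30017305 0.94601823
-0.98851736 -0.13010708 0.07684771
0.78185544 0.22720746 0.58058491
-0.16746005 -0.45048698 0.87693706
-0.15965308 0.87737342 0.45246742
0.13400416 0.93541690 0.32716678
-0.45530931 0.81816052 0.35115068
0.34838703 0.77390978 0.52885739
-0.50333688 -0.27345357 0.81967990
-0.46610002 -0.87080811 0.15634577
0.17989460 0.29436994 0.93860762
-0.90509008 0.03174390 0.42403333
-0.96962132 0.18997914 0.15408575
0.94792460 0.17750571 0.26444410
-0.24153617 -0.13405752 0.96108733
0.50898556 0.25764311 0.82131220
-0.74588731 -0.12048650 0.65508406
0.42454797 -0.84559992 0.32360439
0.04557127 0.01238334 0.99888433
-0.70830827 0.67263242 0.21416123
0.85682586 -0.40274301 0.32194333
-0.44825634 0.40073661 0.79904720
-0.41884052 -0.56886686 0.70778748
0.42847682 -0.35856303 0.82936130
-0.51456392 0.06764878 0.85477928
-0.89763720 -0.44051397 0.01396047
-0.15976007 0.97792752 0.13466438
0.14171031 -0.96947846 0.20007424
-0.88820742 -0.30263248 0.34568940
0.29947320 0.54873119 0.78051898
-0.73340514 -0.62011500 0.27852162
0.65224748 -0.04976182 0.75637093
-0.61112502 0.57200241 0.54711923
0.69441868 -0.70904686 0.12261833
-0.45348436 0.89109276 0.01748214
0.04633694 0.74354059 0.66708341
-0.14903617 -0.74795500 0.64680101
0.97601890 -0.13771136 0.16859032
-0.17020666 -0.91856061 0.35675777
0.14669972 -0.84105832 0.52067274
-0.47109787 -0.75612095 0.45425533
0.68892316 -0.35819453 0.63014408
0.82429771 0.46642178 0.32091122
0.59938329 0.50813283 0.61849874
-0.15356923 -0.98784257 0.02415668
0.41060210 -0.64508363 0.64441681
-0.83806295 0.39766986 0.37350927
0.36845174 -0.03351431 0.92904258
0.61431976 0.70488067 0.35461878
-0.72304343 0.23937430 0.64800319
0.12616308 -0.60069628 0.78945985
0.86696249 -0.08947758 0.49027524
-0.31027891 0.67438897 0.67001979
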
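day,hour,ai
2018-05-09,12:00:00,91.6985
2018-05-09,13:00:00,68.0396
2018-05-09,14:00:00,60.9835
2018-05-09,15:00:00,127.9568
2018-05-09,16:00:00,50.0016
2018-05-09,17:00:00,52.6829
2018-05-09,18:00:00,58.4110
2018-05-09,19:00:00,30.3024
2018-05-09,20:00:00,32.9313
2018-05-09,21:00:00,25.9622
2018-05-09,22:00:00,13.7704
2018-05-09,23:00:00,8.8460
2018-05-09,00:00:00,9.1765
2018-05-09,01:00:00,11.7781
2018-05-09,02:00:00,7.1743
2018-05-09,03:00:00,6.9395
2018-05-09,04:00:00,6.9992
2018-05-09,05:00:00,6.6685
2018-05-09,06:00:00,51.9434
2018-05-09,07:00:00,60.3498
2018-05-09,08:00:00,146.0198
2018-05-09,09:00:00,109.5714
2018-05-09,10:00:00,50.1309
2018-05-09,11:00:00,53.7380
2018-05-10,12:00:00,7.9372
2018-05-10,13:00:00,155.7581
2018-05-10,14:00:00,132.4570
2018-05-10,15:00:00,97.1954
2018-05-10,16:00:00,37.5953
2018-05-10,17:00:00,63.8394
2018-05-10,18:00:00,44.1087
2018-05-10,19:00:00,11.9919
2018-05-10,20:00:00,44.0399
2018-05-10,21:00:00,20.2555
2018-05-10,22:00:00,16.6188
2018-05-10,23:00:00,11.4903
2018-05-10,00:00:00,8.0131
2018-05-10,01:00:00,13.9831
2018-05-10,02:00:00,25.7008
2018-05-10,03:00:00,16.4114
2018-05-10,04:00:00,18.5755
2018-05-10,05:00:00,66.1852
2018-05-10,06:00:00,60.5493
2018-05-10,07:00:00,146.4305
2018-05-10,08:00:00,185.8036
2018-05-10,09:00:00,126.9927
2018-05-10,10:00:00,97.9686
2018-05-10,11:00:00,95.5183
2018-05-11,12:00:00,52.1803
2018-05-11,13:00:00,104.2664
2018-05-11,14:00:00,209.2683
2018-05-11,15:00:00,152.4025
2018-05-11,16:00:00,5.2637
2018-05-11,17:00:00,5.0618
2018-05-11,18:00:00,15.8595
2018-05-11,19:00:00,23.8395
2018-05-11,20:00:00,19.5678
2018-05-11,21:00:00,32.2234
2018-05-11,22:00:00,12.7696
2018-05-11,23:00:00,13.3283
2018-05-11,00:00:00,11.8799
2018-05-11,01:00:00,9.7203
2018-05-11,02:00:00,6.9460
2018-05-11,03:00:00,8.0269
2018-05-11,04:00:00,10.9319
2018-05-11,05:00:00,33.5049
2018-05-11,06:00:00,53.4563
2018-05-11,07:00:00,152.9999
2018-05-11,08:00:00,184.6546
2018-05-11,09:00:00,105.3715
2018-05-11,10:00:00,48.7204
2018-05-11,11:00:00,34.1327
2018-05-12,12:00:00,39.1756
2018-05-12,13:00:00,20.2958
2018-05-12,14:00:00,47.8527
2018-05-12,15:00:00,63.6552
2018-05-12,16:00:00,20.1774
2018-05-12,17:00:00,40.1613
2018-05-12,18:00:00,39.5041
2018-05-12,19:00:00,20.0936
2018-05-12,20:00:00,19.0029
2018-05-12,21:00:00,16.1118
2018-05-12,22:00:00,9.2744
2018-05-12,23:00:00,9.6019
2018-05-12,00:00:00,9.2327
2018-05-12,01:00:00,7.5271
2018-05-12,02:00:00,10.2525
2018-05-12,03:00:00,7.3836
2018-05-12,04:00:00,6.9433
2018-05-12,05:00:00,10.2133
2018-05-12,06:00:00,45.3398
2018-05-12,07:00:00,199.2066
2018-05-12,08:00:00,132.9641
2018-05-12,09:00:00,178.1697
2018-05-12,10:00:00,84.0562
2018-05-12,11:00:00,74.0714
2018-05-13,12:00:00,16.1481
2018-05-13,13:00:00,190.7752
2018-05-13,14:00:00,165.0358
2018-05-13,15:00:00,72.7410
2018-05-13,16:00:00,34.5341
2018-05-13,17:00:00,60.5130
2018-05-13,18:00:00,35.8857
2018-05-13,19:00:00,34.3655
2018-05-13,20:00:00,49.1668
2018-05-13,21:00:00,45.0717
2018-05-13,22:00:00,26.0573
2018-05-13,23:00:00,16.6092
2018-05-13,00:00:00,12.3928
2018-05-13,01:00:00,18.6474
2018-05-13,02:00:00,9.9166
2018-05-13,03:00:00,13.6776
2018-05-13,04:00:00,13.1182
2018-05-13,05:00:00,87.0340
2018-05-13,06:00:00,28.0925
2018-05-13,07:00:00,72.4182
2018-05-13,08:00:00,95.0854
2018-05-13,09:00:00,16.5196
2018-05-13,10:00:00,42.8646
2018-05-13,11:00:00,37.0004
2018-05-14,12:00:00,120.7643
2018-05-14,13:00:00,68.5014
2018-05-14,14:00:00,24.0670
2018-05-14,15:00:00,17.4707
2018-05-14,16:00:00,125.6139
2018-05-14,17:00:00,50.6716
2018-05-14,18:00:00,16.3036
2018-05-14,19:00:00,24.9894
2018-05-14,20:00:00,21.5088
2018-05-14,21:00:00,18.5637
2018-05-14,22:00:00,9.6644
2018-05-14,23:00:00,8.3738
2018-05-14,00:00:00,7.2355
2018-05-14,01:00:00,12.4477
2018-05-14,02:00:00,7.7463
2018-05-14,03:00:00,7.3144
2018-05-14,04:00:00,7.3127
2018-05-14,05:00:00,81.8432
2018-05-14,06:00:00,201.7091
2018-05-14,07:00:00,161.1731
2018-05-14,08:00:00,98.3405
2018-05-14,09:00:00,96.5270
2018-05-14,10:00:00,131.4003
2018-05-14,11:00:00,53.0020
2018-05-15,12:00:00,7.4088
2018-05-15,13:00:00,59.4915
2018-05-15,14:00:00,79.0501
2018-05-15,15:00:00,110.0526
2018-05-15,16:00:00,55.4181
2018-05-15,17:00:00,35.2950
2018-05-15,18:00:00,43.0587
2018-05-15,19:00:00,19.2359
2018-05-15,20:00:00,42.3071
2018-05-15,21:00:00,26.7250
2018-05-15,22:00:00,16.1690
2018-05-15,23:00:00,10.8001
2018-05-15,00:00:00,7.0924
2018-05-15,01:00:00,7.9296
2018-05-15,02:00:00,15.6859
2018-05-15,03:00:00,8.6616
2018-05-15,04:00:00,11.0475
2018-05-15,05:00:00,69.0056
2018-05-15,06:00:00,43.4253
2018-05-15,07:00:00,138.3872
2018-05-15,08:00:00,239.4251
2018-05-15,09:00:00,150.3620
2018-05-15,10:00:00,77.6424
2018-05-15,11:00:00,78.3121
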
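# Deoxyhemoglobin (Hb) molar extinction coefficient
# unit: cm^-1 M^-1; synthetic literature-style curve, 650-950 nm
# near-isosbestic with HbO2 at 800-808 nm (crossing ~804 nm)
wavelength_nm,value
650,3750
652,3642.0614
654,3534.9574
656,3429.5228
658,3326.5921
660,3227
662,3131.3909
664,3039.6477
666,2951.4632
668,2866.53
670,2784.5409
672,2705.1885
674,2628.1655
676,2553.1646
678,2479.8786
680,2408
682,2337.3166
684,2267.996
686,2200.3008
688,2134.4934
690,2070.8366
692,2009.5928
694,1951.0247
696,1895.3948
698,1842.9657
700,1794
702,1748.5496
704,1705.8242
706,1664.8228
708,1624.5443
710,1583.9878
712,1542.1523
714,1498.0367
716,1450.6402
718,1398.9616
720,1342
722,1280.0271
724,1218.4054
726,1163.7702
728,1122.7567
730,1102
732,1105.861
734,1129.6029
736,1166.2142
738,1208.6837
740,1250
742,1284.8407
744,1314.6391
746,1342.517
748,1371.5966
750,1405
752,1444.0627
754,1482.9746
756,1514.1962
758,1531.506
760,1530
762,1506.6667
764,1465.8354
766,1413.6708
768,1356.3375
770,1300
772,1249.5989
774,1205.1782
776,1165.5582
778,1129.5587
780,1096
782,1063.8339
784,1032.5396
786,1001.7285
788,971.01154
790,940
792,908.67369
794,878.48723
796,851.26393
798,828.82708
800,813
802,804.54744
804,800
806,795.64114
808,791
810,786
812,779.32637
814,770.96909
816,761.34862
818,750.88544
820,740
822,729.10512
824,718.58307
826,708.80846
828,700.15589
830,693
832,687.62022
834,683.91529
836,681.6888
838,680.74433
840,680.88544
842,681.91572
844,683.63874
846,685.85807
848,688.3773
850,691
852,693.56436
854,696.047
856,698.45917
858,700.81211
860,703.11705
862,705.38525
864,707.62794
866,709.85636
868,712.08175
870,714.31535
872,716.56841
874,718.85217
876,721.17785
878,723.55672
880,726
882,728.52349
884,731.16119
886,733.95164
888,736.93339
890,740.145
892,743.625
894,747.41196
896,751.54441
898,756.06091
900,761
902,766.35812
904,771.96325
906,777.60124
908,783.05797
910,788.11929
912,792.57106
914,796.19916
916,798.78944
918,800.12777
920,800
922,798.24636
924,794.92452
926,790.14647
928,784.02424
930,776.66984
932,768.19529
934,758.7126
936,748.3338
938,737.17088
940,725.33587
942,712.94079
944,700.09765
946,686.91846
948,673.51524
950,660
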
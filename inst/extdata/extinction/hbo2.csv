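# Oxyhemoglobin (HbO2) molar extinction coefficient
# unit: cm^-1 M^-1; synthetic literature-style curve, 650-950 nm
# near-isosbestic with Hb at 800-808 nm (crossing ~804 nm)
wavelength_nm,value
650,368
652,357.64804
654,347.48407
656,337.69607
658,328.47206
660,320
662,312.4279
664,305.74378
666,299.89564
668,294.83151
670,290.49942
672,286.84736
674,283.82338
676,281.37548
678,279.45168
680,278
682,276.98045
684,276.40097
686,276.28151
688,276.64198
690,277.50234
692,278.88251
694,280.80242
696,283.28202
698,286.34123
700,290
702,294.24637
704,298.94089
706,303.91223
708,308.98904
710,314
712,318.8532
714,323.7745
716,329.06921
718,335.04261
720,342
722,350.14883
724,359.30509
726,369.18694
728,379.51253
730,390
732,400.4555
734,411.03714
736,421.99103
738,433.56328
740,446
742,459.45318
744,473.69835
746,488.41694
748,503.29035
750,518
752,532.29178
754,546.16945
756,559.70122
758,572.95533
760,586
762,598.8997
764,611.70386
766,624.45818
768,637.20833
770,650
772,662.82943
774,675.49511
776,687.74606
778,699.33135
780,710
782,719.57458
784,728.17172
786,735.98157
788,743.19428
790,750
792,756.58425
794,763.11403
796,769.75167
798,776.65954
800,784
802,791.85688
804,800
806,808.13188
808,816
810,824
812,834.34138
814,846.93505
816,860.95803
818,875.58734
820,890
822,903.54896
824,916.29087
826,928.45829
828,940.28381
830,952
832,963.78278
834,975.58148
836,987.28879
838,998.7974
840,1010
842,1020.7919
844,1031.0792
846,1040.7705
848,1049.7746
850,1058
852,1065.3902
854,1072.0271
856,1078.0273
858,1083.5075
860,1088.5843
862,1093.3744
864,1097.9944
866,1102.5609
868,1107.1905
870,1112
872,1117.0802
874,1122.4197
876,1127.9811
878,1133.7273
880,1139.621
882,1145.6251
884,1151.7022
886,1157.8152
888,1163.9269
890,1170
892,1175.9934
894,1181.8506
896,1187.5111
898,1192.9144
900,1198
902,1202.7155
904,1207.0398
906,1210.9602
908,1214.4635
910,1217.5368
912,1220.1672
914,1222.3417
916,1224.0473
918,1225.2711
920,1226
922,1226.2319
924,1226.0077
926,1225.3792
928,1224.398
930,1223.1158
932,1221.5843
934,1219.8553
936,1217.9805
938,1216.0115
940,1214
942,1211.9889
944,1209.9852
946,1207.987
948,1205.9926
950,1204
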
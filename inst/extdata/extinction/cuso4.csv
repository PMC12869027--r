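# Copper sulfate (CuSO4) specific absorption, deoxy-analog surrogate
# unit: cm^-1 per g/L; synthetic stylized curve (not a measured spectrum):
# monotonically increasing over 730-830 nm;
# eps_Cu(800)/eps_Ni(800) = 14.28 exactly
wavelength_nm,value
650,0.7
652,0.70542802
654,0.7108535
656,0.71627391
658,0.72168672
660,0.72708937
662,0.73247935
664,0.73785411
666,0.74321111
668,0.74854783
670,0.75386172
672,0.75915024
674,0.76441087
676,0.76964106
678,0.77483829
680,0.78
682,0.78512456
684,0.79021391
686,0.79527087
688,0.80029826
690,0.80529891
692,0.81027565
694,0.8152313
696,0.82016869
698,0.82509065
700,0.83
702,0.83490054
704,0.8398
706,0.84470707
708,0.84963044
710,0.85457881
712,0.85956087
714,0.86458533
716,0.86966087
718,0.8747962
720,0.88
722,0.88526217
724,0.89049739
726,0.89560151
728,0.90047043
730,0.905
732,0.90911237
734,0.91283481
736,0.91622083
738,0.91932397
740,0.92219776
742,0.92489572
744,0.9274714
746,0.92997832
748,0.93247001
750,0.935
752,0.93760964
754,0.94029154
756,0.94302614
758,0.94579386
760,0.94857514
762,0.95135041
764,0.9541001
766,0.95680464
768,0.95944446
770,0.962
772,0.96446106
774,0.96685492
776,0.96921826
778,0.97158773
780,0.974
782,0.97648319
784,0.97903124
786,0.98162958
788,0.9842636
790,0.98691871
792,0.98958033
794,0.99223386
796,0.99486471
798,0.99745829
800,1
802,1.0024799
804,1.0049066
806,1.0072933
808,1.0096534
810,1.012
812,1.0143438
814,1.0166847
816,1.0190203
818,1.0213479
820,1.0236649
822,1.0259687
824,1.0282567
826,1.0305263
828,1.032775
830,1.035
832,1.0371985
834,1.0393658
836,1.0414973
838,1.0435878
840,1.0456327
842,1.0476269
844,1.0495656
846,1.051444
848,1.0532571
850,1.055
852,1.0566684
854,1.0582599
856,1.0597726
858,1.0612048
860,1.0625544
862,1.0638197
864,1.0649987
866,1.0660897
868,1.0670908
870,1.068
872,1.0688164
874,1.0695419
876,1.0701794
878,1.0707318
880,1.0712019
882,1.0715924
884,1.0719064
886,1.0721466
888,1.0723158
890,1.0724169
892,1.0724527
894,1.0724261
896,1.0723399
898,1.0721969
900,1.072
902,1.0717507
904,1.0714451
906,1.0710781
908,1.0706445
910,1.0701392
912,1.0695569
914,1.0688924
916,1.0681407
918,1.0672965
920,1.0663547
922,1.0653101
924,1.0641575
926,1.0628917
928,1.0615076
930,1.06
932,1.0583667
934,1.0566176
936,1.0547656
938,1.0528235
940,1.0508042
942,1.0487206
944,1.0465855
946,1.0444118
948,1.0422123
950,1.04
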
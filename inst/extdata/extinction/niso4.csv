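# Nickel sulfate (NiSO4) specific absorption, oxy-analog surrogate
# unit: cm^-1 per g/L; synthetic stylized curve (not a measured spectrum):
# the unit spectrum 14.28*eps_Ni rises with wavelength (oxy-analog role)
# and eps_Cu(800)/eps_Ni(800) = 14.28 exactly
wavelength_nm,value
650,0.032870291
652,0.031945639
654,0.031037778
656,0.030163501
658,0.029339598
660,0.028582862
662,0.027906511
664,0.027309475
666,0.026787111
668,0.026334776
670,0.025947827
672,0.02562162
674,0.025351514
676,0.025132864
678,0.024961027
680,0.024831361
682,0.024740293
684,0.024688534
686,0.024677863
688,0.024710061
690,0.024786909
692,0.024910188
694,0.025081678
696,0.025303159
698,0.025576412
700,0.025903218
702,0.026282511
704,0.026701832
706,0.027145879
708,0.027599347
710,0.028046933
712,0.028480428
714,0.028920006
716,0.029392936
718,0.029926489
720,0.030547933
722,0.031275798
724,0.032093649
726,0.03297631
728,0.033898607
730,0.034835363
732,0.035769263
734,0.03671443
736,0.037692848
738,0.038726498
740,0.039837364
742,0.041039021
744,0.04231142
746,0.043626106
748,0.04495462
750,0.046268507
752,0.04754507
754,0.048784643
756,0.049993321
758,0.051177197
760,0.052342366
762,0.053494585
764,0.054638272
766,0.055777506
768,0.056916367
770,0.058058938
772,0.059204881
774,0.060336197
776,0.061430471
778,0.062465285
780,0.063418224
782,0.06427344
784,0.065041348
786,0.065738935
788,0.066383185
790,0.066991082
792,0.067579197
794,0.068162446
796,0.06875533
798,0.069372351
800,0.070028011
802,0.070729799
804,0.071457154
806,0.072183506
808,0.072886297
810,0.073600869
812,0.074524576
814,0.075649461
816,0.076902014
818,0.078208724
820,0.079496084
822,0.080706297
824,0.081844422
826,0.082931234
828,0.083987507
830,0.085034014
832,0.086086468
834,0.087140345
836,0.088186059
838,0.089214025
840,0.090214657
842,0.091178608
844,0.092097483
846,0.092963126
848,0.093767379
850,0.094502087
852,0.095162187
854,0.095755003
856,0.096290952
858,0.096780453
860,0.097233923
862,0.097661781
864,0.098074443
866,0.09848233
868,0.098895857
870,0.099325444
872,0.099779218
874,0.10025615
876,0.1007529
878,0.10126616
880,0.10179259
882,0.10232888
884,0.1028717
886,0.10341773
888,0.10396363
890,0.10450609
892,0.10504143
894,0.1055646
896,0.1060702
898,0.10655283
900,0.10700709
902,0.10742828
904,0.10781454
906,0.10816471
908,0.10847763
910,0.10875215
912,0.1089871
914,0.10918133
916,0.10933367
918,0.10944298
920,0.10950809
922,0.1095288
924,0.10950878
926,0.10945264
928,0.10936499
930,0.10925047
932,0.10911368
934,0.10895924
936,0.10879177
938,0.1086159
940,0.10843623
942,0.1082566
944,0.10807762
946,0.10789914
948,0.107721
950,0.10754302
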
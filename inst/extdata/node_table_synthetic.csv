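"name","x","y","z","space","x_tal","y_tal","z_tal"
"Parahippocampal_Gyrus_R",-22.5,-22.5,1.5,"MNI",-22.1716,-22.49765,3.2688
"Parahippocampal_Gyrus/Hippocampus_L",-22.5,-7.5,1.5,"MNI",-22.1281,-8.40365,4.3968
"Postcentral_Gyrus_L",-22.5,7.5,1.5,"MNI",-22.0846,5.69035,5.5248
"Precentral_Gyrus_R",-22.5,22.5,1.5,"MNI",-22.0411,19.78435,6.6528
"Angular_Gyrus_L",-7.5,-22.5,1.5,"MNI",-8.1361,-22.59515,3.4233
"Precuneus_L",-7.5,-7.5,1.5,"MNI",-8.0926,-8.50115,4.5513
"Medial_Frontal_Gyrus/Anterior_Cingulate_L",-7.5,7.5,1.5,"MNI",-8.0491,5.59285,5.6793
"Middle_Temporal_Gyrus_R_#1",-7.5,22.5,1.5,"MNI",-8.0056,19.68685,6.8073
"Middle_Temporal_Gyrus_R_#2",7.5,-22.5,1.5,"MNI",5.8994,-22.69265,3.5778
"Cerebellum_R",7.5,-7.5,1.5,"MNI",5.9429,-8.59865,4.7058
"Inferior_Temporal_Gyrus_L",7.5,7.5,1.5,"MNI",5.9864,5.49535,5.8338
"Inferior_Parietal_Lobule_L",7.5,22.5,1.5,"MNI",6.0299,19.58935,6.9618
"Fusiform_Gyrus_L",22.5,-22.5,1.5,"MNI",19.9349,-22.79015,3.7323
"Superior_Temporal_Gyrus_L",22.5,-7.5,1.5,"MNI",19.9784,-8.69615,4.8603
"Inferior_Frontal_Gyrus_R",22.5,7.5,1.5,"MNI",20.0219,5.39785,5.9883
"Parahippocampal_Gyrus_L",22.5,22.5,1.5,"MNI",20.0654,19.49185,7.1163
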
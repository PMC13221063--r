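"site","depth","width","velocity","temperature","pH","ec","tds","salinity","do","bod","turbidity","sand","silt","clay","gravel","true_suitability","abundance"
"W01",78.9736,10.9121,0.0421506,28.0264,8.57968,1988.84,563.65,1.10582,7.33213,3.65436,8.55549,0.412721,0.0682269,0.519052,0.826251,0.00382526,1052
"W02",80.2874,4.79886,0.210543,28.7476,8.33319,2576.62,821.271,0.893647,8.16929,2.84345,9.68227,0.317451,0.127024,0.555525,0.776367,0.0223983,7602
"W03",41.8822,6.66064,0.162179,31.2638,8.1334,2149.44,545.063,0.563703,9.22228,3.76558,13.0856,0.381428,0.45139,0.167181,0.285278,0.0808545,26491
"W04",73.9964,10.9601,0.363238,30.2024,8.14272,1780.06,1056.31,0.419981,8.64813,4.11194,13.4243,0.708099,0.120226,0.171675,0.233335,0.0208826,6444
"W05",62.863,11.304,0.184318,29.3664,8.17894,2321.91,359.423,0.415612,8.68073,3.98231,16.1408,0.860894,0.0575969,0.0815093,0.66804,0.0145495,2645
"W06",55.6267,3.55739,0.336042,29.5688,8.44928,1058.72,719.492,0.635218,6.79893,3.52815,9.35494,0.630296,0.177572,0.192131,0.672625,0.07097,17169
"W07",68.4587,6.77497,0.297662,28.1348,7.92726,1215.25,855.562,0.997427,6.79621,3.6544,20.3114,0.66106,0.144895,0.194045,0.826114,0.0192791,5778
"W08",32.9453,7.54299,0.326312,31.5047,8.42416,2280.72,353.238,0.330239,7.58915,3.65681,21.2177,0.418197,0.0794105,0.502393,0.713872,0.00226284,423
"W09",63.7625,10.6363,0.161362,29.5543,8.37409,2022.51,921.381,0.53857,10.1353,2.8421,5.98064,0.621142,0.312436,0.0664216,0.119997,0.0189938,4012
"W10",66.5988,3.74839,0.277216,31.4473,8.01989,1156.43,506.368,1.26303,10.228,3.38061,16.242,0.407733,0.350802,0.241465,0.258975,0.00491055,1453
"W11",52.0068,11.4,0.0115399,31.1959,8.08276,778.45,703.368,1.25564,9.20333,3.77044,19.986,0.571132,0.340692,0.0881766,0.175209,0.00243565,762
"W12",67.4276,11.02,0.334837,30.3039,8.26009,964.979,984.096,1.06409,9.17293,4.09999,13.7126,0.490232,0.392028,0.11774,0.705698,0.0331966,9483
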
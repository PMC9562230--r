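wine_id,perceived_quality,alpha0.8_n1.0,alpha0.7_n1.0,alpha0.8_n0.8,alpha0.75_n1.0,alpha0.75_n0.9
WAR16,5.02,5.848,4.521,4.678,5.154,4.639
MCH16,5.7,3.688,3.333,2.950,3.520,3.168
WCR16,6.55,6.849,5.418,5.479,6.101,5.491
WE16,6.09,6.271,5.051,5.017,5.636,5.072
OFRB316,6.35,6.428,4.997,5.142,5.678,5.110
OFRCP16,6.52,6.576,5.077,5.261,5.790,5.211
MG16,5.52,6.203,5.039,4.962,5.601,5.041
MG13,5.98,5.813,4.748,4.651,5.263,4.736
CG16,5.89,6.768,5.346,5.415,6.025,5.423
OMD16,6.07,6.920,5.471,5.536,6.163,5.546
NN16,6.02,6.768,5.360,5.415,6.032,5.429
WPP16,6.23,5.327,4.278,4.262,4.782,4.304
WPP13,5.43,4.863,4.071,3.890,4.459,4.013
CPB16,6.34,3.554,3.267,2.843,3.421,3.079
MPR16,4.72,5.257,4.353,4.205,4.792,4.313
OQR16,5.72,6.790,5.398,5.432,6.065,5.458
OQR13,5.3,6.730,5.322,5.384,5.995,5.396
NS16,4.82,6.742,5.242,5.394,5.954,5.359
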
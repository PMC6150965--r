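population_id,pair_rank,homologue,mean_tl_um,sd_tl_um,printed_kl_um
CI,1,1,6.29,0.82,83.06
CI,1,2,6.06,0.83,83.06
CI,2,1,5.4,0.81,83.06
CI,2,2,5.03,0.76,83.06
CI,3,1,4.48,0.58,83.06
CI,3,2,4.28,0.51,83.06
CI,4,1,4.13,0.51,83.06
CI,4,2,4.04,0.5,83.06
CI,5,1,3.98,0.51,83.06
CI,5,2,3.91,0.51,83.06
CI,6,1,3.84,0.46,83.06
CI,6,2,3.76,0.45,83.06
CI,7,1,3.71,0.45,83.06
CI,7,2,3.64,0.45,83.06
CI,8,1,3.59,0.45,83.06
CI,8,2,3.52,0.4,83.06
CI,9,1,3.46,0.4,83.06
CI,9,2,3.41,0.39,83.06
CI,10,1,3.35,0.4,83.06
CI,10,2,3.18,0.45,83.06
TO,1,1,6.06,0.87,82.72
TO,1,2,5.77,0.81,82.72
TO,2,1,5.1,0.62,82.72
TO,2,2,4.92,0.59,82.72
TO,3,1,4.35,0.69,82.72
TO,3,2,4.23,0.66,82.72
TO,4,1,4.11,0.66,82.72
TO,4,2,4.05,0.63,82.72
TO,5,1,3.98,0.62,82.72
TO,5,2,3.92,0.61,82.72
TO,6,1,3.85,0.62,82.72
TO,6,2,3.77,0.61,82.72
TO,7,1,3.73,0.6,82.72
TO,7,2,3.7,0.58,82.72
TO,8,1,3.67,0.57,82.72
TO,8,2,3.6,0.56,82.72
TO,9,1,3.56,0.55,82.72
TO,9,2,3.5,0.53,82.72
TO,10,1,3.45,0.55,82.72
TO,10,2,3.4,0.54,82.72
BG,1,1,5.3,0.78,73.38
BG,1,2,4.93,0.77,73.38
BG,2,1,4.48,0.71,73.38
BG,2,2,4.34,0.7,73.38
BG,3,1,3.9,0.61,73.38
BG,3,2,3.8,0.54,73.38
BG,4,1,3.67,0.46,73.38
BG,4,2,3.59,0.46,73.38
BG,5,1,3.53,0.44,73.38
BG,5,2,3.46,0.44,73.38
BG,6,1,3.41,0.44,73.38
BG,6,2,3.38,0.43,73.38
BG,7,1,3.34,0.45,73.38
BG,7,2,3.31,0.44,73.38
BG,8,1,3.28,0.43,73.38
BG,8,2,3.26,0.43,73.38
BG,9,1,3.18,0.44,73.38
BG,9,2,3.13,0.41,73.38
BG,10,1,3.09,0.44,73.38
BG,10,2,3,0.46,73.38
MC,1,1,5.25,0.69,68.63
MC,1,2,4.9,0.61,68.63
MC,2,1,4.31,0.58,68.63
MC,2,2,4.1,0.57,68.63
MC,3,1,3.61,0.43,68.63
MC,3,2,3.53,0.45,68.63
MC,4,1,3.42,0.4,68.63
MC,4,2,3.3,0.42,68.63
MC,5,1,3.26,0.41,68.63
MC,5,2,3.21,0.4,68.63
MC,6,1,3.16,0.4,68.63
MC,6,2,3.1,0.36,68.63
MC,7,1,3.07,0.36,68.63
MC,7,2,3.04,0.38,68.63
MC,8,1,3,0.37,68.63
MC,8,2,2.98,0.36,68.63
MC,9,1,2.94,0.38,68.63
MC,9,2,2.91,0.37,68.63
MC,10,1,2.85,0.34,68.63
MC,10,2,2.7,0.39,68.63
CC,1,1,4.87,0.6,66.08
CC,1,2,4.58,0.63,66.08
CC,2,1,4.17,0.41,66.08
CC,2,2,3.8,0.37,66.08
CC,3,1,3.42,0.48,66.08
CC,3,2,3.34,0.4,66.08
CC,4,1,3.28,0.31,66.08
CC,4,2,3.21,0.32,66.08
CC,5,1,3.2,0.32,66.08
CC,5,2,3.14,0.29,66.08
CC,6,1,3.07,0.28,66.08
CC,6,2,3.04,0.29,66.08
CC,7,1,3,0.28,66.08
CC,7,2,2.99,0.29,66.08
CC,8,1,2.96,0.28,66.08
CC,8,2,2.92,0.29,66.08
CC,9,1,2.89,0.29,66.08
CC,9,2,2.8,0.26,66.08
CC,10,1,2.77,0.27,66.08
CC,10,2,2.62,0.25,66.08
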
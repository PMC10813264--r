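# Published athlete psychometric study: per-subject experimental values
# (75% angular threshold in degrees, psychometric slope in 1/deg, mean
# reaction time in seconds, each with uncertainty) alongside the matched
# simulated values and the four model parameters (k, tau, delta, tau_a)
# selected by grid search.  Ditto marks of the printed table (grouped
# subjects sharing one simulated state) are expanded to explicit values;
# `group` identifies the shared simulated state.  `rotation_active` marks
# the one subject simulated with rotation detectors enabled.  `suspect`
# flags values preserved verbatim from the printed source that are likely
# typographical errors (subject A03's noise level 0.340, plausibly 0.034).
subject,group,thr_exp,thr_exp_err,thr_sim,thr_sim_err,slope_exp,slope_exp_err,slope_sim,slope_sim_err,rt_exp,rt_exp_err,rt_sim,rt_sim_err,k,tau,delta,tau_a,rotation_active,suspect
C12,G01,4.041,1.06,5.252,0.20,0.261,0.030,0.263,0.0049,0.994,0.07,1.148,0.0005,4,0.025,0.022,1.22,FALSE,FALSE
A10,G01,4.176,1.08,5.252,0.20,0.252,0.029,0.263,0.0049,0.929,0.04,1.148,0.0005,4,0.025,0.022,1.22,FALSE,FALSE
B04,G01,4.506,1.11,5.252,0.20,0.246,0.028,0.263,0.0049,1.194,0.05,1.148,0.0005,4,0.025,0.022,1.22,FALSE,FALSE
B01,G01,4.805,1.13,5.252,0.20,0.243,0.027,0.263,0.0049,1.443,0.06,1.148,0.0005,4,0.025,0.022,1.22,FALSE,FALSE
A15,G02,5.321,1.15,5.317,0.19,0.242,0.025,0.276,0.005,1.131,0.08,1.106,0.0002,2,0.033,0.032,1.34,FALSE,FALSE
B05,G03,5.361,1.05,5.201,0.18,0.284,0.028,0.307,0.0055,1.165,0.01,1.146,0.0002,4,0.037,0.030,1.40,FALSE,FALSE
B09,G04,6.602,1.42,6.872,0.27,0.188,0.021,0.180,0.0036,1.001,0.03,1.020,0.0003,4,0.025,0.034,1.22,FALSE,FALSE
A11,G04,6.637,1.52,6.872,0.27,0.171,0.023,0.180,0.0036,1.013,0.05,1.020,0.0003,4,0.025,0.034,1.22,FALSE,FALSE
A06,G05,6.609,1.22,6.793,0.25,0.233,0.020,0.200,0.0038,0.989,0.03,0.883,0.0002,8,0.033,0.032,1.10,FALSE,FALSE
A01,G06,7.000,1.52,6.909,0.25,0.175,0.02,0.205,0.0038,1.007,0.01,1.089,0.0003,8,0.030,0.034,1.40,FALSE,FALSE
C07,G06,7.097,1.42,6.909,0.25,0.192,0.02,0.205,0.0038,1.169,0.07,1.089,0.0003,8,0.030,0.034,1.40,FALSE,FALSE
C11,G06,7.165,1.39,6.909,0.25,0.197,0.02,0.205,0.0038,1.146,0.08,1.089,0.0003,8,0.030,0.034,1.40,FALSE,FALSE
B14,G07,7.692,1.80,7.701,0.36,0.147,0.018,0.131,0.0032,1.005,0.04,1.076,0.0009,1,0.024,0.026,0.96,FALSE,FALSE
B08,G07,7.753,1.81,7.701,0.36,0.146,0.018,0.131,0.0032,0.923,0.06,1.076,0.0009,1,0.024,0.026,0.96,FALSE,FALSE
A02,G07,7.837,1.87,7.701,0.36,0.141,0.018,0.131,0.0032,1.133,0.04,1.076,0.0009,1,0.024,0.026,0.96,FALSE,FALSE
A13,G07,7.873,1.69,7.701,0.36,0.159,0.018,0.131,0.0032,1.203,0.08,1.076,0.0009,1,0.024,0.026,0.96,FALSE,FALSE
B11,G08,8.132,2.00,8.459,0.39,0.132,0.017,0.124,0.0031,1.065,0.02,1.116,0.0009,1,0.024,0.028,1.00,FALSE,FALSE
C13,G08,8.594,2.09,8.459,0.39,0.128,0.017,0.124,0.0031,1.147,0.05,1.116,0.0009,1,0.024,0.028,1.00,FALSE,FALSE
C04,G09,9.173,1.78,9.685,0.35,0.158,0.017,0.148,0.003,0.887,0.03,0.880,0.0003,16,0.025,0.034,1.04,FALSE,FALSE
B03,G10,9.191,2.64,9.292,0.45,0.103,0.016,0.111,0.0029,1.141,0.07,1.181,0.0012,2,0.024,0.028,1.00,FALSE,FALSE
C06,G11,9.543,2.34,9.709,0.41,0.118,0.016,0.123,0.0029,0.899,0.05,1.078,0.001,2,0.024,0.030,0.90,FALSE,FALSE
B07,G11,9.589,2.86,9.709,0.41,0.096,0.016,0.123,0.0029,1.264,0.07,1.078,0.001,2,0.024,0.030,0.90,FALSE,FALSE
C08,G12,9.747,1.70,9.838,0.32,0.170,0.017,0.167,0.0031,0.947,0.05,0.944,0.0003,32,0.033,0.032,1.22,FALSE,FALSE
A03,G13,10.490,1.56,12.076,0.43,0.130,0.011,0.130,0.0028,0.964,0.04,0.858,0.0006,32,0.025,0.340,0.88,FALSE,TRUE
A04,G13,10.801,2.20,12.076,0.43,0.132,0.016,0.130,0.0028,0.757,0.05,0.858,0.0006,32,0.025,0.340,0.88,FALSE,TRUE
A07,G13,10.843,2.26,12.076,0.43,0.128,0.016,0.130,0.0028,0.871,0.05,0.858,0.0006,32,0.025,0.340,0.88,FALSE,TRUE
A05,G14,10.770,2.72,10.747,0.41,0.105,0.015,0.130,0.0029,1.098,0.06,1.068,0.0014,4,0.024,0.028,0.80,FALSE,FALSE
C01,G14,10.830,2.61,10.747,0.41,0.110,0.016,0.130,0.0029,0.909,0.06,1.068,0.0014,4,0.024,0.028,0.80,FALSE,FALSE
A08,G15,12.132,2.76,12.722,0.45,0.109,0.015,0.124,0.0027,0.793,0.03,0.962,0.0013,4,0.024,0.032,0.66,FALSE,FALSE
B02,G15,12.173,2.68,12.722,0.45,0.113,0.015,0.124,0.0027,0.936,0.05,0.962,0.0013,4,0.024,0.032,0.66,FALSE,FALSE
B06,G15,12.525,2.82,12.722,0.45,0.108,0.015,0.124,0.0027,0.888,0.06,0.962,0.0013,4,0.024,0.032,0.66,FALSE,FALSE
B13,G16,12.860,3.94,11.549,0.49,0.078,0.015,0.109,0.0028,1.032,0.06,1.067,0.0011,2,0.024,0.034,0.84,FALSE,FALSE
B10,G17,13.160,3.02,13.363,0.56,0.103,0.015,0.101,0.0027,1.044,0.06,1.208,0.0009,64,0.025,0.036,1.15,TRUE,FALSE
A14,G18,16.617,4.89,17.319,0.74,0.071,0.014,0.088,0.0025,1.058,0.06,1.154,0.0017,4,0.024,0.038,0.60,FALSE,FALSE
A09,G18,17.194,5.84,17.319,0.74,0.061,0.014,0.088,0.0025,1.014,0.04,1.154,0.0017,4,0.024,0.038,0.60,FALSE,FALSE
C02,G18,17.787,5.36,17.319,0.74,0.068,0.014,0.088,0.0025,0.842,0.04,1.154,0.0017,4,0.024,0.038,0.60,FALSE,FALSE
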
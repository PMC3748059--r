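week,precip_mm,tmin_c,tavg_c,tmax_c,hmin_pct,havg_pct,hmax_pct,wind_ms
2009-W11,11.91,21.95,26.77,32.04,60.45,80.97,96.32,3.58
2009-W12,119.92,20.66,24.77,31.68,66.9,84.93,100,3.24
2009-W13,10.8,21.09,26.88,32.03,67.42,88.54,100,3.84
2009-W14,17.53,21.1,26.55,31.57,67.77,86.49,100,3.25
2009-W15,91.03,20.49,24.23,29.64,60.13,81.38,98.09,3.4
2009-W16,152.21,18.22,24.41,31.23,60.13,81.82,95.47,3.7
2009-W17,0,18.59,22.66,27.46,64.52,85.12,98.53,3.53
2009-W18,20.81,18.46,22.62,28.75,67.58,87.77,100,3.29
2009-W19,18.46,19.44,23.27,28.28,58.93,80.95,95.56,3.13
2009-W20,84.1,19.36,23.41,28.65,52.43,74.44,88.37,2.97
2009-W21,1.19,19.3,24.02,29.23,51.09,72.06,86.05,3.79
2009-W22,9.55,18.84,24.26,30.39,49.9,70,86.05,3.44
2009-W23,70.42,18.98,23.41,29.4,55.13,76.93,91.2,2.77
2009-W24,190.2,18.96,23.8,30.16,57.03,77.65,92.7,2.6
2009-W25,13.21,16.53,21.3,27.65,61.73,84.35,98.51,2.24
2009-W26,0,18.86,24.8,32.03,59.42,77.67,93.29,2.76
2009-W27,38.05,19.44,26.27,31.82,56.02,76.19,90.49,2.62
2009-W28,55.28,19.29,23.43,26.91,59.49,81.55,97.19,2.82
2009-W29,0,18.09,24.62,29.68,58.7,77.9,92.34,2.89
2009-W30,0,18.78,25.49,30.37,57.69,75.23,92.56,1.23
2009-W31,0,18.11,23.29,28.56,57.89,79.1,94.68,1.46
2009-W32,0,17.8,23.52,29.94,53.89,73.23,86.09,3.07
2009-W33,6.09,16.33,19.94,24.98,52.99,72.51,89.26,2.87
2009-W34,0,18.26,23.64,28.49,54.43,75.96,90.97,2.59
2009-W35,55.64,17.97,22.53,28.42,46.04,69.72,85.09,2.77
2009-W36,0,19.62,24.49,30.55,46.81,67.18,83.95,2.87
2009-W37,45.55,20.43,25.87,31.18,44.57,66.38,81.97,1.97
2009-W38,0,19.24,25.07,30.9,43.13,60.03,78.2,2.19
2009-W39,0,19.12,24.09,29.99,42.69,63.13,77.6,2.66
2009-W40,25.88,20.16,27.27,33.06,45.93,63.44,78.97,2.65
2009-W41,0,18.56,24.03,29.07,46.87,64.45,80.12,2.41
2009-W42,0,18.34,23.18,29.27,44.32,66.87,82.93,2.32
2009-W43,32.44,17.85,23.2,26.88,48.13,69.55,85.64,1.88
2009-W44,0,18.2,23.12,29.11,50.37,71.6,87.35,2.04
2009-W45,0,18.34,22.46,28.29,51.98,71.43,85.03,2.5
2009-W46,18.63,19.48,24.89,32.03,52.93,71.18,85.79,2.22
2009-W47,0,19.69,25.45,31.16,56.42,77.41,92.6,2.46
2009-W48,33.07,18.42,23.72,29.31,53.22,71.71,86.22,2.71
2009-W49,0,19.22,24.52,30.97,51.9,76.07,91.56,3.22
2009-W50,0,18.4,23.52,29.61,55.51,75.93,90.08,2.23
2009-W51,95.46,17.67,23.35,28.85,57.67,78.47,94.66,2.63
2009-W52,11.32,19.27,23.24,28.73,60.88,78.65,94,3.3
2009-W53,61.69,18.34,24.27,29.88,59.83,80.96,96.72,3.32
2010-W01,29.14,19.39,23.66,28.31,61.42,83.54,98.37,2.27
2010-W02,0,18.97,24.23,30.72,64.28,85.08,99.36,2.65
2010-W03,61.12,21.05,26.67,31.73,60.84,81.23,98.08,3.56
2010-W04,249.75,21.66,26.85,32.11,66.48,89.28,100,2.9
2010-W05,16.29,20.98,24.74,30.79,62.65,84.1,98.24,3.17
2010-W06,126.3,21.83,26.85,32.03,57.86,79.18,93.46,2.88
2010-W07,216.97,22.02,27.29,32.7,59.71,81.71,99,3.64
2010-W08,103.37,20.57,26.36,33.08,61.94,82.79,97.76,4.09
2010-W09,348,20.69,26.09,31.08,60.72,86.05,100,3.89
2010-W10,283.47,20.05,25.51,30.83,59.03,79.89,93.76,3.9
2010-W11,32.62,21.04,26.95,33.66,59.06,81.08,95.67,3.59
2010-W12,238.73,20.53,24.97,30.19,64.41,86.17,100,4.59
2010-W13,3.64,20.62,25.12,30.18,57.86,79.3,95.19,4.5
2010-W14,43.11,19.63,24.62,30.33,53.82,75.8,90.54,3.28
2010-W15,157.15,19.27,24.54,30.53,53.61,74.47,90.4,2.63
2010-W16,79.71,20.09,26.21,31.19,60.35,77.55,92.79,2.97
2010-W17,323.06,19.38,23.69,29.08,63.6,82.62,97.93,2.95
2010-W18,55.37,19.74,24.04,29.44,60.04,84.09,100,3.22
2010-W19,301.55,20.18,25.8,30.53,60.25,83.62,97.91,2.99
2010-W20,0.18,20,24.67,30.19,61.75,81.88,98.15,2.79
2010-W21,247.41,19.7,24.53,31.38,61.87,78.15,94.57,3.42
2010-W22,0,17.98,23.46,29.67,61.7,80.78,97.88,3.68
2010-W23,45.92,18.31,22.82,27.74,60.19,78.09,93.57,3.67
2010-W24,0,16.89,21.31,27.09,59.28,76.9,92.3,3.27
2010-W25,71.92,18.88,23.68,28.98,53.04,74.86,90.15,3.47
2010-W26,196.52,17.83,22.52,27.89,59.58,80.08,96.04,2.35
2010-W27,50.41,18.26,22.71,28.9,56.23,78.83,94.66,1.85
2010-W28,0,18.8,24.5,30.48,55.9,74.08,88.84,2.85
2010-W29,18.88,18.52,23.14,29.38,49.81,68.5,84.67,2.51
2010-W30,0,19.63,24.68,30.55,48.85,70.18,85.99,2.68
2010-W31,0,18.03,23.14,28,51.37,73.52,89.46,3.51
2010-W32,0,18.3,21.82,26.92,50.83,70.85,89.33,2.79
2010-W33,0,17,22.28,26.81,50.66,69.42,84.85,2.1
2010-W34,0,19.29,25.49,31.48,45.72,68.98,83.47,0.78
2010-W35,0,19.2,24.18,30.77,48.05,71.04,86.65,1.5
2010-W36,0,18.1,22.48,26.68,46.39,68.38,83.16,1.86
2010-W37,0,18.57,24.62,30.18,41.94,63.55,77.72,2.6
2010-W38,0,16.92,22.13,28.04,46.17,64.56,79.21,2.23
2010-W39,136.74,18.62,24.43,29.76,46.98,64.03,79.27,2.17
2010-W40,0,17.01,22.18,27.02,45.36,69.05,85.32,2.23
2010-W41,0,15.69,21.18,25.87,47.59,68.37,83.9,2.51
2010-W42,0,16.45,22.61,29.14,42.75,61.74,75.85,2.81
2010-W43,57.23,17.88,23.41,28.74,51.93,74.67,89.58,2.32
2010-W44,80.59,17.95,23.25,29.7,44.41,63.72,76.99,2.58
2010-W45,52.69,17.33,21.79,26.77,48.29,67.85,82.71,2.77
2010-W46,0,18.98,24.44,30.97,49.3,70.31,83.84,2.75
2010-W47,0,21.3,25.96,31.9,47.42,65.49,78.92,3.44
2010-W48,30.09,18.41,25.16,30.68,51.21,70.7,86.96,2.22
2010-W49,0,20.21,25.49,31.92,51.66,70.27,85.15,2.84
2010-W50,46.1,19.44,23.8,29.01,58.13,80.31,95.41,3.48
2010-W51,20.49,20.54,26.85,32.06,54.52,75.35,91.06,2.6
2010-W52,0,18.48,23.11,28.61,60.06,79.9,94.45,2.88
2011-W01,189.38,18.91,22.64,28.06,61.4,83.82,98.66,2.49
2011-W02,0,18.55,22.72,28.1,57.73,77.96,92.37,2.64
2011-W03,35.99,18.89,23.92,29.28,58.46,78.41,93.09,2.93
2011-W04,7.98,18.58,23.23,28.05,57.03,77.55,91.39,3
2011-W05,86.5,19.9,25.27,31.54,53.17,72.43,88.48,4.12
2011-W06,27.38,21.6,26.42,31.25,62.8,83.2,99.04,3.67
2011-W07,203.57,20.96,24.48,29.37,67.75,89.54,100,2.83
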
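task,dimension,statistic,timepoint_s,value_m,printed_mark
T1,x_front,median,0,0.83,reference
T1,x_front,median,3,1.12,reference
T1,x_front,median,10,1.41,reference
T1,x_front,maximum,0,1.32,reference
T1,x_front,maximum,3,1.89,reference
T1,x_front,maximum,10,2.58,reference
T1,y_diameter,median,0,0.84,reference
T1,y_diameter,median,3,0.97,reference
T1,y_diameter,median,10,0.58,reference
T1,y_diameter,maximum,0,1.16,reference
T1,y_diameter,maximum,3,1.43,reference
T1,y_diameter,maximum,10,1.62,reference
T2,x_front,median,0,0.97,higher
T2,x_front,median,3,0.90,lower
T2,x_front,median,10,0.97,lower
T2,x_front,maximum,0,1.38,comparable
T2,x_front,maximum,3,1.44,lower
T2,x_front,maximum,10,1.50,lower
T2,y_diameter,median,0,0.47,lower
T2,y_diameter,median,3,0.42,lower
T2,y_diameter,median,10,0.04,lower
T2,y_diameter,maximum,0,0.77,lower
T2,y_diameter,maximum,3,1.00,lower
T2,y_diameter,maximum,10,1.14,lower
T3,x_front,median,0,1.06,higher
T3,x_front,median,3,0.93,lower
T3,x_front,median,10,1.01,lower
T3,x_front,maximum,0,1.35,comparable
T3,x_front,maximum,3,1.62,lower
T3,x_front,maximum,10,2.17,lower
T3,y_diameter,median,0,0.57,lower
T3,y_diameter,median,3,0.53,lower
T3,y_diameter,median,10,0.23,lower
T3,y_diameter,maximum,0,0.97,lower
T3,y_diameter,maximum,3,0.83,lower
T3,y_diameter,maximum,10,0.72,lower
T4,x_front,median,0,0.65,lower
T4,x_front,median,3,0.81,lower
T4,x_front,median,10,0.70,lower
T4,x_front,maximum,0,1.40,comparable
T4,x_front,maximum,3,1.74,higher
T4,x_front,maximum,10,2.28,higher
T4,y_diameter,median,0,0.56,comparable
T4,y_diameter,median,3,0.67,higher
T4,y_diameter,median,10,0.65,higher
T4,y_diameter,maximum,0,0.78,lower
T4,y_diameter,maximum,3,0.77,comparable
T4,y_diameter,maximum,10,0.81,comparable
T5,x_front,median,0,1.17,higher
T5,x_front,median,3,1.28,higher
T5,x_front,median,10,1.36,higher
T5,x_front,maximum,0,1.31,comparable
T5,x_front,maximum,3,1.51,lower
T5,x_front,maximum,10,1.93,lower
T5,y_diameter,median,0,0.59,comparable
T5,y_diameter,median,3,0.70,higher
T5,y_diameter,median,10,0.70,higher
T5,y_diameter,maximum,0,0.74,lower
T5,y_diameter,maximum,3,0.96,higher
T5,y_diameter,maximum,10,1.29,higher
T6,x_front,median,0,0.65,lower
T6,x_front,median,3,0.42,lower
T6,x_front,median,10,0.39,lower
T6,x_front,maximum,0,1.16,lower
T6,x_front,maximum,3,1.14,lower
T6,x_front,maximum,10,1.46,lower
T6,y_diameter,median,0,0.19,lower
T6,y_diameter,median,3,0.08,lower
T6,y_diameter,median,10,0.08,lower
T6,y_diameter,maximum,0,0.65,lower
T6,y_diameter,maximum,3,0.55,lower
T6,y_diameter,maximum,10,0.62,lower
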
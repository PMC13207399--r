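cohort,model,case,metric,value
medium,RD,1,r2,66.04
medium,RD,2,r2,71.41
medium,RD,3,r2,54.52
medium,RD,4,r2,71.97
medium,RD,5,r2,79.67
medium,RD,6,r2,74.48
medium,RD,7,r2,39.66
medium,RD,8,r2,58.28
medium,RD,9,r2,68.12
medium,RD,10,r2,60
medium,RL,1,r2,55.33
medium,RL,2,r2,68.45
medium,RL,3,r2,22.22
medium,RL,4,r2,26.25
medium,RL,5,r2,34.81
medium,RL,6,r2,49.45
medium,RL,7,r2,9.09
medium,RL,8,r2,69.06
medium,RL,9,r2,78.01
medium,RL,10,r2,33.76
medium,RM,1,r2,65.33
medium,RM,2,r2,76.05
medium,RM,3,r2,66.91
medium,RM,4,r2,72.41
medium,RM,5,r2,56.06
medium,RM,6,r2,65.84
medium,RM,7,r2,26.04
medium,RM,8,r2,19.42
medium,RM,9,r2,76.21
medium,RM,10,r2,65.94
medium,CD,1,r2,52.65
medium,CD,2,r2,82.21
medium,CD,3,r2,71.46
medium,CD,4,r2,76.8
medium,CD,5,r2,81.06
medium,CD,6,r2,69.39
medium,CD,7,r2,-7.27
medium,CD,8,r2,48.19
medium,CD,9,r2,69.75
medium,CD,10,r2,66.69
medium,CL,1,r2,44.54
medium,CL,2,r2,54.2
medium,CL,3,r2,9.34
medium,CL,4,r2,75.13
medium,CL,5,r2,76.6
medium,CL,6,r2,70.68
medium,CL,7,r2,50.83
medium,CL,8,r2,26.89
medium,CL,9,r2,79.79
medium,CL,10,r2,77.83
medium,CM,1,r2,42.3
medium,CM,2,r2,72.06
medium,CM,3,r2,61.36
medium,CM,4,r2,75.51
medium,CM,5,r2,61.01
medium,CM,6,r2,72.99
medium,CM,7,r2,-10.6
medium,CM,8,r2,68.6
medium,CM,9,r2,77.95
medium,CM,10,r2,70.87
medium,RD,1,pcc,85.34
medium,RD,2,pcc,87.52
medium,RD,3,pcc,86.11
medium,RD,4,pcc,85.84
medium,RD,5,pcc,89.49
medium,RD,6,pcc,89.84
medium,RD,7,pcc,76.19
medium,RD,8,pcc,78.22
medium,RD,9,pcc,89.76
medium,RD,10,pcc,81.47
medium,RL,1,pcc,91.57
medium,RL,2,pcc,85.12
medium,RL,3,pcc,82.56
medium,RL,4,pcc,78.28
medium,RL,5,pcc,83.1
medium,RL,6,pcc,83.24
medium,RL,7,pcc,74.25
medium,RL,8,pcc,89.51
medium,RL,9,pcc,89.97
medium,RL,10,pcc,83.65
medium,RM,1,pcc,84.83
medium,RM,2,pcc,89.25
medium,RM,3,pcc,87.87
medium,RM,4,pcc,85.17
medium,RM,5,pcc,79.26
medium,RM,6,pcc,86.07
medium,RM,7,pcc,71.77
medium,RM,8,pcc,78.48
medium,RM,9,pcc,92
medium,RM,10,pcc,85.8
medium,CD,1,pcc,81.36
medium,CD,2,pcc,91.7
medium,CD,3,pcc,90.1
medium,CD,4,pcc,87.66
medium,CD,5,pcc,90.1
medium,CD,6,pcc,90.16
medium,CD,7,pcc,60.17
medium,CD,8,pcc,75.11
medium,CD,9,pcc,91.96
medium,CD,10,pcc,88.24
medium,CL,1,pcc,87.49
medium,CL,2,pcc,89.73
medium,CL,3,pcc,85.2
medium,CL,4,pcc,88.04
medium,CL,5,pcc,89.9
medium,CL,6,pcc,86.11
medium,CL,7,pcc,75.18
medium,CL,8,pcc,86.16
medium,CL,9,pcc,90.08
medium,CL,10,pcc,89.99
medium,CM,1,pcc,79.49
medium,CM,2,pcc,87.15
medium,CM,3,pcc,87.48
medium,CM,4,pcc,87.18
medium,CM,5,pcc,80.36
medium,CM,6,pcc,87.77
medium,CM,7,pcc,58.96
medium,CM,8,pcc,84.48
medium,CM,9,pcc,91.37
medium,CM,10,pcc,88.73
medium,RD,1,rmse,0.81
medium,RD,2,rmse,0.86
medium,RD,3,rmse,0.81
medium,RD,4,rmse,1.06
medium,RD,5,rmse,0.8
medium,RD,6,rmse,0.79
medium,RD,7,rmse,1.21
medium,RD,8,rmse,0.89
medium,RD,9,rmse,1.23
medium,RD,10,rmse,1.28
medium,RL,1,rmse,0.93
medium,RL,2,rmse,0.91
medium,RL,3,rmse,1.06
medium,RL,4,rmse,1.72
medium,RL,5,rmse,1.43
medium,RL,6,rmse,1.11
medium,RL,7,rmse,1.48
medium,RL,8,rmse,0.77
medium,RL,9,rmse,1.03
medium,RL,10,rmse,1.65
medium,RM,1,rmse,0.82
medium,RM,2,rmse,0.79
medium,RM,3,rmse,0.69
medium,RM,4,rmse,1.05
medium,RM,5,rmse,1.18
medium,RM,6,rmse,0.91
medium,RM,7,rmse,1.33
medium,RM,8,rmse,1.24
medium,RM,9,rmse,1.07
medium,RM,10,rmse,1.18
medium,CD,1,rmse,0.96
medium,CD,2,rmse,0.68
medium,CD,3,rmse,0.64
medium,CD,4,rmse,0.96
medium,CD,5,rmse,0.77
medium,CD,6,rmse,0.86
medium,CD,7,rmse,1.61
medium,CD,8,rmse,0.99
medium,CD,9,rmse,1.2
medium,CD,10,rmse,1.17
medium,CL,1,rmse,1.03
medium,CL,2,rmse,1.09
medium,CL,3,rmse,1.15
medium,CL,4,rmse,1
medium,CL,5,rmse,0.86
medium,CL,6,rmse,0.85
medium,CL,7,rmse,1.09
medium,CL,8,rmse,1.18
medium,CL,9,rmse,0.98
medium,CL,10,rmse,0.95
medium,CM,1,rmse,1.05
medium,CM,2,rmse,0.85
medium,CM,3,rmse,0.75
medium,CM,4,rmse,0.99
medium,CM,5,rmse,1.11
medium,CM,6,rmse,0.81
medium,CM,7,rmse,1.63
medium,CM,8,rmse,0.77
medium,CM,9,rmse,1.03
medium,CM,10,rmse,1.09
medium,RD,1,nrmse,0.14
medium,RD,2,nrmse,0.13
medium,RD,3,nrmse,0.18
medium,RD,4,nrmse,0.14
medium,RD,5,nrmse,0.12
medium,RD,6,nrmse,0.14
medium,RD,7,nrmse,0.21
medium,RD,8,nrmse,0.17
medium,RD,9,nrmse,0.15
medium,RD,10,nrmse,0.17
medium,RL,1,nrmse,0.15
medium,RL,2,nrmse,0.13
medium,RL,3,nrmse,0.23
medium,RL,4,nrmse,0.23
medium,RL,5,nrmse,0.21
medium,RL,6,nrmse,0.2
medium,RL,7,nrmse,0.26
medium,RL,8,nrmse,0.14
medium,RL,9,nrmse,0.12
medium,RL,10,nrmse,0.22
medium,RM,1,nrmse,0.14
medium,RM,2,nrmse,0.12
medium,RM,3,nrmse,0.15
medium,RM,4,nrmse,0.14
medium,RM,5,nrmse,0.18
medium,RM,6,nrmse,0.16
medium,RM,7,nrmse,0.23
medium,RM,8,nrmse,0.23
medium,RM,9,nrmse,0.13
medium,RM,10,nrmse,0.16
medium,CD,1,nrmse,0.16
medium,CD,2,nrmse,0.1
medium,CD,3,nrmse,0.14
medium,CD,4,nrmse,0.13
medium,CD,5,nrmse,0.12
medium,CD,6,nrmse,0.15
medium,CD,7,nrmse,0.28
medium,CD,8,nrmse,0.19
medium,CD,9,nrmse,0.14
medium,CD,10,nrmse,0.16
medium,CL,1,nrmse,0.17
medium,CL,2,nrmse,0.16
medium,CL,3,nrmse,0.25
medium,CL,4,nrmse,0.14
medium,CL,5,nrmse,0.13
medium,CL,6,nrmse,0.15
medium,CL,7,nrmse,0.19
medium,CL,8,nrmse,0.22
medium,CL,9,nrmse,0.12
medium,CL,10,nrmse,0.13
medium,CM,1,nrmse,0.17
medium,CM,2,nrmse,0.13
medium,CM,3,nrmse,1.15
medium,CM,4,nrmse,0.14
medium,CM,5,nrmse,0.17
medium,CM,6,nrmse,0.14
medium,CM,7,nrmse,0.29
medium,CM,8,nrmse,0.14
medium,CM,9,nrmse,0.12
medium,CM,10,nrmse,0.15
small,RD,1,r2,14.76
small,RD,2,r2,31.85
small,RL,1,r2,45.35
small,RL,2,r2,21.49
small,RM,1,r2,42.88
small,RM,2,r2,22.93
small,CD,1,r2,-25.5
small,CD,2,r2,21.18
small,CL,1,r2,22.59
small,CL,2,r2,12.77
small,CM,1,r2,11.64
small,CM,2,r2,32.09
small,RD,1,pcc,60.43
small,RD,2,pcc,81.49
small,RL,1,pcc,75.91
small,RL,2,pcc,49.61
small,RM,1,pcc,70.35
small,RM,2,pcc,53.86
small,CD,1,pcc,53.16
small,CD,2,pcc,54.7
small,CL,1,pcc,73.92
small,CL,2,pcc,46.36
small,CM,1,pcc,74.61
small,CM,2,pcc,59.03
small,RD,2,rmse,3.65
small,RD,13,rmse,8.06
small,RL,2,rmse,2.92
small,RL,13,rmse,8.65
small,RM,2,rmse,2.99
small,RM,13,rmse,8.57
small,CD,2,rmse,4.43
small,CD,13,rmse,8.67
small,CL,2,rmse,3.48
small,CL,13,rmse,9.12
small,CM,2,rmse,3.72
small,CM,13,rmse,8.04
small,RD,2,nrmse,0.2413
small,RD,13,nrmse,0.2008
small,RL,2,nrmse,0.1932
small,RL,13,nrmse,0.2155
small,RM,2,nrmse,0.1975
small,RM,13,nrmse,0.2135
small,CD,2,nrmse,0.2928
small,CD,13,nrmse,0.2159
small,CL,2,nrmse,0.23
small,CL,13,nrmse,0.2272
small,CM,2,nrmse,0.2457
small,CM,13,nrmse,0.2004
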
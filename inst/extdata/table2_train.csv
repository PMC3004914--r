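drug_code,cc_uM,n,Inh,Inh_sem,IC50_uM,Rev,Rev_sem,UD,UD_sem,tau_on_s,tau_on_sem,tau_off_s,tau_off_sem,dropout
FLX,30,5,0.41,0.08,43.09,0.33,0.09,1.14,0.01,53.38,4.86,39.34,12.4,0
SRT,30,7,0.68,0.07,14.31,0.23,0.02,1.42,0.03,26.55,7.93,29.55,10.5,0
PRX,30,6,0.65,0.06,16.23,0.34,0.08,1.46,0.04,32.07,5.25,35.99,5.86,0
AMI,30,7,0.56,0.07,23.46,0.50,0.09,1.66,0.05,10.54,1.42,16.95,3.84,0
IMI,30,5,0.61,0.04,19.46,0.43,0.05,1.51,0.05,16.97,2.24,16.03,2.26,0
DMI,30,5,0.62,0.03,18.28,0.43,0.06,1.32,0.06,32.02,3.93,51.82,4.99,0
MPR,10,5,0.30,0.04,23.03,0.34,0.07,1.17,0.04,22.07,2.39,25.21,1.1,0
NIS,100,6,0.57,0.06,75.72,0.66,0.05,1.33,0.04,20.71,2.25,23.41,3,0
MIA,30,5,0.41,0.06,42.77,0.7,0.13,1.25,0.04,17.78,3.35,16.98,3.35,0
MRZ,100,7,0.43,0.08,132.28,0.89,0.03,1.14,0.01,3.99,0.01,7.47,1.05,0
BPR,100,4,0.15,0.04,565.02,0.92,0.03,1.04,0.02,4.6,1.16,12.45,2.77,0
VFX,100,4,0.12,0.02,726.99,0.89,0.06,1.05,0.01,4.85,2.04,5.2,1.63,0
NFZ,30,4,0.39,0.09,46.43,0.51,0.09,1.22,0.04,8.75,0.57,10.93,0.63,0
TRZ,100,5,0.16,0.04,365.11,0.67,0.10,1.02,0.01,8.25,2.42,16.64,3.02,0
HAL,30,4,0.59,0.09,20.44,0.59,0.02,1.56,0.07,11.91,2.75,24.11,5.9,0
CPM,30,4,0.41,0.08,47.28,0.07,0.03,1.30,0.06,14.81,2.44,9.67,2.18,0
CHX,30,4,0.28,0.05,42.54,0.18,0.05,1.25,0.07,7.24,3.85,14.41,1.11,0
CLZ,100,5,0.51,0.03,94.54,0.63,0.02,1.31,0.02,10.38,0.51,16.4,2.71,0
CBZ,300,5,0.29,0.02,718,0.87,0.05,0.98,0.02,3,,10.01,2.33,0
LTG,300,4,0.25,0.03,904.86,0.85,0.09,0.97,0.01,8.19,1.23,18.1,1.32,0
DPH,300,6,0.18,0.03,1392.4,0.75,0.07,1.01,0.01,5.20,1.20,15.96,3.86,0
BPV,100,4,0.60,0.04,67.72,0.75,0.05,1.62,0.05,7.95,0.05,16.73,1.43,0
LID,300,6,0.23,0.02,1084.4,0.95,0.06,1.14,0.03,3,,6,0.31,0
MEX,300,4,0.57,0.04,230.54,0.78,0.04,1.39,0.03,8.6,0.87,12.93,0.72,0
FLC,300,4,0.82,0.03,67.63,0.57,0.04,1.34,0.02,20.04,1.26,64.97,5.51,0
RAN,100,4,0.16,0.04,354.55,0.89,0.07,1.21,0.02,8.13,1.75,13.24,1.98,0
MEM,100,5,0.32,0.02,230.49,0.93,0.05,0.99,0.03,3.51,0.22,8.98,1.61,0
RIL,30,4,0.27,0.07,80.98,0.52,0.08,0.95,0.03,3.9,0.07,17.6,5.42,0
DIC,100,6,0.56,0.1,561.19,0.95,0.04,1.01,0.04,7.19,1.89,26.43,5.31,0
RIT,30,5,0.15,0.06,23.62,0.37,0.02,1.09,0.00,14.38,2.64,22.28,6.47,0
AMB,100,5,0.51,0.1,95.94,0.81,0.06,1.24,0.02,5.74,1.14,6.78,1.1,0
SIL,100,6,0.45,0.06,120.65,0.8,0.04,1.16,0.02,4.1,0.56,15.21,4.12,0
TOL,100,5,0.23,0.01,335.95,0.95,0.03,1.14,0.04,5.57,1.57,7.42,1.47,0
FLR,100,4,0.85,0.04,17.65,0.004,0.001,1.06,0.03,132.8,23.5,500,,0
LIF,30,4,0.78,0.06,5.29,0.01,0.001,1.02,0.03,96.5,36.8,500,,0
MEC,100,4,0.05,0.01,2757.1,,,,,,,,,1
TIA,300,4,0.07,0.02,3985.7,,,,,,,,,1
TOP,300,4,0.07,0.01,3985.7,,,,,,,,,1
ZON,300,5,0.09,0.01,3033.3,,,,,,,,,1
PRC,300,5,0.14,0.03,2007.7,,,,,,,,,1
GAB,300,4,0.03,0.02,14700,,,,,,,,,1
MCL,100,4,0.09,0.02,1011.1,,,,,,,,,1
NIA,100,4,0.03,0.02,3233.3,,,,,,,,,1
DPR,300,4,0.22,0.1,354.55,,,,,,,,,1
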
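drug_code,cc_uM,n,Inh_150,Inh_150_sem,dV_half_mV,dV_half_sem,Kr_uM,Ki_dV_uM,Ki_kapp_uM,SD,Kr_lit_uM,Ki_lit_uM
FLX,30,4,0.13,0.02,-10.1,2.87,210.5,4.08,6.05,34.8,89.35,1.2
SRT,30,4,0.35,0.02,-15,1.01,56.41,1.47,2.1,26.9,,1.7
PRX,30,5,0.55,0.09,-11.4,3.77,24.19,1.99,0.73,33,17,1.45
AMI,10,3,0.08,0.03,-11.3,2.47,133.9,1.45,3.34,40.1,38.11,0.52
AMI,30,3,0.20,0.02,-11.2,0.76,124.9,3.69,4.92,25.4,,
AMI,100,3,0.59,0.05,-18,1.89,69.62,1.65,2,34.8,,
IMI,30,4,0.25,0.08,-9.37,2.89,107.2,3.82,5.98,17.9,26.46,0.89
DMI,30,4,0.35,0.04,-5.87,0.53,57.03,8.06,4.37,13.1,29.24,1.15
MPR,10,4,0.12,0.03,-4.11,0.88,89.66,5.63,3.17,28.3,18.33,1.45
NIS,100,4,0.34,0.02,-6.68,0.52,194.2,19.1,7.1,27.3,,
MIA,30,4,0.18,0.03,-11.4,1.86,145.9,4.5,4.99,29.2,190,1.3
MRZ,100,4,0.24,0.01,-12.8,0.20,316.8,5.63,7.62,41.6,,
BPR,100,4,0.16,0.04,-6.97,1.27,603.6,26,25.5,23.6,,
VFX,100,5,0.11,0.02,-4.66,1.11,888.7,59.5,63.4,14,8,0.64
NFZ,30,4,0.09,0.03,-17.4,1.75,567.4,0.87,0.92,616,,
TRZ,100,4,0.19,0.04,-9.32,1.74,452,16.6,14.3,31.7,1000,111
HAL,30,5,0.22,0.03,-4.72,1.24,113.5,13.8,2.96,38.4,7,0.28
CPM,30,7,0.32,0.05,-18.4,0.69,69.64,0.29,0.82,85.4,3.18,0.19
CHX,30,4,0.20,0.05,-15.8,2.18,128.5,0.73,1.74,74.1,,
CLZ,100,4,0.29,0.02,-8.35,1.42,248.6,11,12.4,20.1,,
CBZ,300,4,0.21,0.02,-11.4,0.19,1169,39.9,26.4,44.3,946.1,21.8
LTG,300,4,0.12,0.01,-10.3,1.35,2267,31.3,36.7,61.8,1562,15.1
DPH,300,4,0.12,0.04,-4.93,1.25,2536,208.2,70.8,18.4,701.1,16.2
BPV,100,6,0.14,0.01,-11.3,0.79,618.9,5.85,7.79,79.5,291,20.1
LID,300,4,0.09,0.01,-5.35,1.28,3192,89.6,65.7,48.6,686.7,17.7
MEX,300,4,0.32,0.03,-10.3,1.82,638.2,26.8,17.9,35.8,395.1,12.4
FLC,300,8,0.82,0.01,-12.4,0.94,64.69,7.9,5.7,11.3,354.9,5.55
RAN,300,4,0.42,0.11,-5.52,1.00,435.5,66.8,10.7,40.7,1000,75
MEM,100,6,0.29,0.02,-1.77,0.54,242.2,109.8,28.5,8.5,178,6.67
RIL,30,3,0.08,0.01,-15,0.47,373.6,2.17,3.43,108.8,62.4,0.49
RIL,100,3,0.22,0.01,-29.2,0.42,359.5,0.48,1.63,219.5,,
DIC,100,4,0.03,0.01,-3.73,1.00,3119,81,87.84,35.5,784.9,6.5
RIT,30,5,0.13,0.02,-7.28,0.66,205.7,7.1,6.13,33.6,,
AMB,100,4,0.33,0.01,-9.87,0.90,200.9,12.2,17.6,11.4,110,8.17
SIL,100,4,0.43,0.03,-7.66,0.86,132.8,14,6.7,19.8,340,34.9
TOL,100,5,0.21,0.02,-6.47,1.74,391.1,30.9,21.1,18.6,384.3,5.07
FLR,10,5,0.04,0.00,-9.59,1.33,241,2,1.75,137.4,,
LIF,1,4,0.02,0.00,-4.39,0.50,55.77,0.92,0.5,111.5,10.16,0.19
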
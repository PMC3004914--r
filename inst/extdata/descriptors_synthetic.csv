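drug_code,logP,logD7_3,pKa,MW,PSA,aromatic_atom_count,min_projection_area,acid
FLX,4,1.5,9.8,309.3,21.3,12,42,FALSE
SRT,5.1,2.9,9.5,306.2,12,12,44,FALSE
PRX,3.6,1.1,9.8,329.4,39.7,12,45,FALSE
AMI,4.9,2.8,9.4,277.4,3.2,12,41,FALSE
IMI,4.5,2.4,9.4,280.4,6.5,12,42,FALSE
DMI,4,1.1,10.2,266.4,15.3,12,41,FALSE
MPR,4.9,2,10.2,277.4,12,12,42,FALSE
NIS,4,1.6,9.7,271.4,21.3,12,40,FALSE
MIA,3.8,3.45,7.4,264.4,6.5,12,40,FALSE
MRZ,2.9,2.35,7.7,265.4,19.4,12,40,FALSE
BPR,3.6,2.82,8,239.7,29.1,6,36,FALSE
VFX,3.2,1.1,9.4,277.4,32.7,6,40,FALSE
NFZ,4.7,4.58,6.8,470,57,17,58,FALSE
TRZ,3,2.9,6.7,371.9,42.4,15,50,FALSE
HAL,4.3,3.26,8.3,375.9,40.5,12,48,FALSE
CPM,5.4,3.49,9.2,318.9,31.8,13,44,FALSE
CHX,5.2,3.69,8.8,315.9,28.5,13,44,FALSE
CLZ,3.2,2.79,7.5,326.8,30.9,15,46,FALSE
CBZ,2.5,2.5,2.3,236.3,46.3,12,38,FALSE
LTG,2.5,2.49,5.7,256.1,90.7,12,37,FALSE
DPH,2.5,2.4,8.3,252.3,58.2,12,38,TRUE
BPV,3.4,2.54,8.1,288.4,32.3,6,41,FALSE
LID,2.3,1.52,8,234.3,32.3,6,35,FALSE
MEX,2.6,0.79,9.1,179.3,35.3,6,31,FALSE
FLC,4.6,2.6,9.3,414.3,59.6,6,52,FALSE
RAN,2.8,2.55,7.2,427.5,72,12,54,FALSE
MEM,3.3,-0.1,10.7,179.3,26,0,32,FALSE
RIL,3.5,3.5,3.8,234.2,58.4,9,36,FALSE
DIC,4.5,1.3,4,296.1,49.3,12,42,TRUE
RIT,4.9,4.55,7.4,477.6,55,16,58,FALSE
AMB,2.8,1.85,8.2,378.1,58.3,6,46,FALSE
SIL,2.5,0.59,9.2,287.4,23,6,40,FALSE
TOL,3,1.39,8.9,245.4,20.3,6,37,FALSE
FLR,5.9,5.12,8,404.5,6.5,18,54,FALSE
LIF,6.1,5.62,7.6,438.6,33,17,56,FALSE
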
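drug_code,name,therapeutic_class,mechanism,concentration_tested_uM,plasma_concentration_uM
FLX,Fluoxetine,antidepressant,SSRI,30,1.099
SRT,Sertraline,antidepressant,SSRI,30,0.409
PRX,Paroxetine,antidepressant,SSRI,30,0.22
AMI,Amitriptyline,antidepressant,TCA,30,0.204
IMI,Imipramine,antidepressant,TCA,30,0.631
DMI,Desipramine,antidepressant,TCA,30,0.330
MPR,Maprotiline,antidepressant,NRI,10,0.797
NIS,Nisoxetine,antidepressant,NRI,100,0.159
MIA,Mianserin,antidepressant,NaSSA,30,0.037
MRZ,Mirtazapine,antidepressant,NaSSA,100,0.158
BPR,Bupropion,antidepressant,NDRI,100,0.514
VFX,Venlafaxine,antidepressant,SNRI,100,0.532
NFZ,Nefazodone,antidepressant,SNRI,30,3.007
TRZ,Trazodone,antidepressant,augmenter,100,3.673
NIA,Nialamide,antidepressant,MAO inhibitor,100,
MCL,Moclobemide,antidepressant,MAO-A inhibitor,100,1.484
HAL,Haloperidol,antipsychotic,D2 antagonist,30,0.053
CPM,Chlorpromazine,antipsychotic,D2 antagonist,30,0.281
CHX,Chlorprothixene,antipsychotic,D2 antagonist,30,0.200
CLZ,Clozapine,antipsychotic,D4 antagonist,100,1.671
TIA,Tiapride,antipsychotic,D2 antagonist,300,1.535
CBZ,Carbamazepine,antiepileptic,SCI,300,39.362
LTG,Lamotrigine,antiepileptic,SCI,300,9.762
DPH,Phenytoin,antiepileptic,SCI,300,39.64
TOP,Topiramate,antiepileptic,SCI,300,16.21
ZON,Zonisamide,antiepileptic,SCI,300,133.82
GAB,Gabapentin,antiepileptic,Ca-channel inhibitor,300,23.359
BPV,Bupivacaine,local anesthetic,SCI,100,2.462
LID,Lidocaine,local anesthetic,SCI,300,12.925
MEX,Mexiletine,antiarrhythmic 1b,SCI,300,9.271
FLC,Flecainide,antiarrhythmic 1c,SCI,300,0.965
PRC,Procainamide,antiarrhythmic 1a,SCI,300,9.198
RAN,Ranolazine,antianginal,SCI,100,7.173
MEM,Memantine,Alzheimer's disease,NMDA antagonist,100,0.075
RIL,Riluzole,amyotrophic lateral sclerosis,SCI,30,0.739
DIC,Diclofenac,NSAID,COX inhibitor,100,6.287
RIT,Ritanserin,anxiolytic,5HT2 antagonist,30,0.299
AMB,Ambroxol,analgesic,SCI,100,0.362
SIL,Silperisone,muscle relaxant,SCI,100,1.484
TOL,Tolperisone,muscle relaxant,SCI,100,1.508
FLR,Flunarizine,migraine,Ca-channel inhibitor,100,0.113
LIF,Lifarizine,neuroprotective,SCI,30,0.046
MEC,Mecamylamine,smoking cessation,nACh antagonist,100,0.118
DPR,Deprenyl,Parkinson's disease,MAO-B inhibitor,300,0.005
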
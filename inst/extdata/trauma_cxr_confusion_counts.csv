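finding,reader,tp,fp,tn,fn
pneumothorax,radiologist,57,8,1224,115
pneumothorax,ai,67,2,1227,104
pneumomediastinum,radiologist,3,1,1376,24
pneumomediastinum,ai,3,0,1373,24
rib_fracture,radiologist,113,13,1042,236
rib_fracture,ai,143,75,977,205
clavicle_fracture,radiologist,43,3,1322,36
clavicle_fracture,ai,44,37,1284,35
humerus_fracture,radiologist,21,2,1371,10
humerus_fracture,ai,10,8,1361,21
scapula_fracture,radiologist,15,5,1344,40
scapula_fracture,ai,19,64,1281,36
lobar_collapse,radiologist,4,1,1366,33
lobar_collapse,ai,13,21,1343,23
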
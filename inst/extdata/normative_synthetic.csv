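channel,band,metric,age_lo,age_hi,mean,sd
Fp1,Theta,absolute_power,60,75,3.6004,1.0801
Fp2,Theta,absolute_power,60,75,3.6004,1.0801
F7,Theta,absolute_power,60,75,3.6004,1.0801
F3,Theta,absolute_power,60,75,3.6004,1.0801
Fz,Theta,absolute_power,60,75,3.6004,1.0801
F4,Theta,absolute_power,60,75,3.6004,1.0801
F8,Theta,absolute_power,60,75,3.6004,1.0801
T3,Theta,absolute_power,60,75,3.6004,1.0801
C3,Theta,absolute_power,60,75,3.6004,1.0801
Cz,Theta,absolute_power,60,75,3.6004,1.0801
C4,Theta,absolute_power,60,75,3.6004,1.0801
T4,Theta,absolute_power,60,75,3.6004,1.0801
T5,Theta,absolute_power,60,75,3.6004,1.0801
P3,Theta,absolute_power,60,75,3.6004,1.0801
Pz,Theta,absolute_power,60,75,3.6004,1.0801
P4,Theta,absolute_power,60,75,3.6004,1.0801
T6,Theta,absolute_power,60,75,3.6004,1.0801
O1,Theta,absolute_power,60,75,3.6004,1.0801
O2,Theta,absolute_power,60,75,3.6004,1.0801
Oz,Theta,absolute_power,60,75,3.6004,1.0801
Fp1,Alpha1,absolute_power,60,75,2.078,0.6234
Fp2,Alpha1,absolute_power,60,75,2.078,0.6234
F7,Alpha1,absolute_power,60,75,2.078,0.6234
F3,Alpha1,absolute_power,60,75,2.078,0.6234
Fz,Alpha1,absolute_power,60,75,2.078,0.6234
F4,Alpha1,absolute_power,60,75,2.078,0.6234
F8,Alpha1,absolute_power,60,75,2.078,0.6234
T3,Alpha1,absolute_power,60,75,2.078,0.6234
C3,Alpha1,absolute_power,60,75,2.078,0.6234
Cz,Alpha1,absolute_power,60,75,2.078,0.6234
C4,Alpha1,absolute_power,60,75,2.078,0.6234
T4,Alpha1,absolute_power,60,75,2.078,0.6234
T5,Alpha1,absolute_power,60,75,2.078,0.6234
P3,Alpha1,absolute_power,60,75,2.7015,0.8104
Pz,Alpha1,absolute_power,60,75,2.7015,0.8104
P4,Alpha1,absolute_power,60,75,2.7015,0.8104
T6,Alpha1,absolute_power,60,75,2.078,0.6234
O1,Alpha1,absolute_power,60,75,2.7015,0.8104
O2,Alpha1,absolute_power,60,75,2.7015,0.8104
Oz,Alpha1,absolute_power,60,75,2.7015,0.8104
Fp1,Alpha2,absolute_power,60,75,2.9606,0.8882
Fp2,Alpha2,absolute_power,60,75,2.9606,0.8882
F7,Alpha2,absolute_power,60,75,2.9606,0.8882
F3,Alpha2,absolute_power,60,75,2.9606,0.8882
Fz,Alpha2,absolute_power,60,75,2.9606,0.8882
F4,Alpha2,absolute_power,60,75,2.9606,0.8882
F8,Alpha2,absolute_power,60,75,2.9606,0.8882
T3,Alpha2,absolute_power,60,75,2.9606,0.8882
C3,Alpha2,absolute_power,60,75,2.9606,0.8882
Cz,Alpha2,absolute_power,60,75,2.9606,0.8882
C4,Alpha2,absolute_power,60,75,2.9606,0.8882
T4,Alpha2,absolute_power,60,75,2.9606,0.8882
T5,Alpha2,absolute_power,60,75,2.9606,0.8882
P3,Alpha2,absolute_power,60,75,3.8487,1.1546
Pz,Alpha2,absolute_power,60,75,3.8487,1.1546
P4,Alpha2,absolute_power,60,75,3.8487,1.1546
T6,Alpha2,absolute_power,60,75,2.9606,0.8882
O1,Alpha2,absolute_power,60,75,3.8487,1.1546
O2,Alpha2,absolute_power,60,75,3.8487,1.1546
Oz,Alpha2,absolute_power,60,75,3.8487,1.1546
Fp1,Theta,absolute_power,76,120,3.6092,1.0828
Fp2,Theta,absolute_power,76,120,3.6092,1.0828
F7,Theta,absolute_power,76,120,3.6092,1.0828
F3,Theta,absolute_power,76,120,3.6092,1.0828
Fz,Theta,absolute_power,76,120,3.6092,1.0828
F4,Theta,absolute_power,76,120,3.6092,1.0828
F8,Theta,absolute_power,76,120,3.6092,1.0828
T3,Theta,absolute_power,76,120,3.6092,1.0828
C3,Theta,absolute_power,76,120,3.6092,1.0828
Cz,Theta,absolute_power,76,120,3.6092,1.0828
C4,Theta,absolute_power,76,120,3.6092,1.0828
T4,Theta,absolute_power,76,120,3.6092,1.0828
T5,Theta,absolute_power,76,120,3.6092,1.0828
P3,Theta,absolute_power,76,120,3.6092,1.0828
Pz,Theta,absolute_power,76,120,3.6092,1.0828
P4,Theta,absolute_power,76,120,3.6092,1.0828
T6,Theta,absolute_power,76,120,3.6092,1.0828
O1,Theta,absolute_power,76,120,3.6092,1.0828
O2,Theta,absolute_power,76,120,3.6092,1.0828
Oz,Theta,absolute_power,76,120,3.6092,1.0828
Fp1,Alpha1,absolute_power,76,120,2.2377,0.6713
Fp2,Alpha1,absolute_power,76,120,2.2377,0.6713
F7,Alpha1,absolute_power,76,120,2.2377,0.6713
F3,Alpha1,absolute_power,76,120,2.2377,0.6713
Fz,Alpha1,absolute_power,76,120,2.2377,0.6713
F4,Alpha1,absolute_power,76,120,2.2377,0.6713
F8,Alpha1,absolute_power,76,120,2.2377,0.6713
T3,Alpha1,absolute_power,76,120,2.2377,0.6713
C3,Alpha1,absolute_power,76,120,2.2377,0.6713
Cz,Alpha1,absolute_power,76,120,2.2377,0.6713
C4,Alpha1,absolute_power,76,120,2.2377,0.6713
T4,Alpha1,absolute_power,76,120,2.2377,0.6713
T5,Alpha1,absolute_power,76,120,2.2377,0.6713
P3,Alpha1,absolute_power,76,120,2.909,0.8727
Pz,Alpha1,absolute_power,76,120,2.909,0.8727
P4,Alpha1,absolute_power,76,120,2.909,0.8727
T6,Alpha1,absolute_power,76,120,2.2377,0.6713
O1,Alpha1,absolute_power,76,120,2.909,0.8727
O2,Alpha1,absolute_power,76,120,2.909,0.8727
Oz,Alpha1,absolute_power,76,120,2.909,0.8727
Fp1,Alpha2,absolute_power,76,120,2.3917,0.7175
Fp2,Alpha2,absolute_power,76,120,2.3917,0.7175
F7,Alpha2,absolute_power,76,120,2.3917,0.7175
F3,Alpha2,absolute_power,76,120,2.3917,0.7175
Fz,Alpha2,absolute_power,76,120,2.3917,0.7175
F4,Alpha2,absolute_power,76,120,2.3917,0.7175
F8,Alpha2,absolute_power,76,120,2.3917,0.7175
T3,Alpha2,absolute_power,76,120,2.3917,0.7175
C3,Alpha2,absolute_power,76,120,2.3917,0.7175
Cz,Alpha2,absolute_power,76,120,2.3917,0.7175
C4,Alpha2,absolute_power,76,120,2.3917,0.7175
T4,Alpha2,absolute_power,76,120,2.3917,0.7175
T5,Alpha2,absolute_power,76,120,2.3917,0.7175
P3,Alpha2,absolute_power,76,120,3.1092,0.9328
Pz,Alpha2,absolute_power,76,120,3.1092,0.9328
P4,Alpha2,absolute_power,76,120,3.1092,0.9328
T6,Alpha2,absolute_power,76,120,2.3917,0.7175
O1,Alpha2,absolute_power,76,120,3.1092,0.9328
O2,Alpha2,absolute_power,76,120,3.1092,0.9328
Oz,Alpha2,absolute_power,76,120,3.1092,0.9328
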
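# random_coil_shifts v1 — DSS-referenced random-coil 1H/13C correlations of
# the 20 proteinogenic amino acids in denatured (urea) proteins, standard
# literature values. The two X-Pro anchor rows (pre_pro = TRUE) are the
# proline-perturbed Ca-Ha positions of Ser and Thr preceding a proline.
# CH3 correlations are omitted (outside the default spectral window and
# never usable as per-proton references here).
residue,label,c13_ppm,h1_ppm,multiplicity,protons_in_signal,pre_pro
A,Ala Ca-Ha,52.5,4.32,CH,1,FALSE
R,Arg Ca-Ha,56.0,4.34,CH,1,FALSE
R,Arg Cd-Hd,43.2,3.21,CH2,2,FALSE
N,Asn Ca-Ha,53.1,4.74,CH,1,FALSE
N,Asn Cb-Hb,38.9,2.83,CH2,2,FALSE
D,Asp Ca-Ha,54.2,4.64,CH,1,FALSE
D,Asp Cb-Hb,41.1,2.72,CH2,2,FALSE
C,Cys Ca-Ha,58.2,4.55,CH,1,FALSE
C,Cys Cb-Hb,28.0,2.98,CH2,2,FALSE
Q,Gln Ca-Ha,55.7,4.34,CH,1,FALSE
Q,Gln Cg-Hg,33.8,2.38,CH2,2,FALSE
E,Glu Ca-Ha,56.6,4.35,CH,1,FALSE
E,Glu Cg-Hg,36.1,2.28,CH2,2,FALSE
G,Gly Ca-Ha,45.1,3.96,CH2,2,FALSE
H,His Ca-Ha,55.0,4.73,CH,1,FALSE
H,His Cb-Hb,29.0,3.16,CH2,2,FALSE
I,Ile Ca-Ha,61.1,4.17,CH,1,FALSE
I,Ile Cb-Hb,38.8,1.89,CH,1,FALSE
L,Leu Ca-Ha,55.1,4.38,CH,1,FALSE
L,Leu Cb-Hb,42.4,1.62,CH2,2,FALSE
K,Lys Ca-Ha,56.2,4.32,CH,1,FALSE
K,Lys Ce-He,42.0,2.99,CH2,2,FALSE
M,Met Ca-Ha,55.4,4.48,CH,1,FALSE
M,Met Cg-Hg,32.1,2.54,CH2,2,FALSE
F,Phe Ca-Ha,57.7,4.62,CH,1,FALSE
F,Phe Cb-Hb,39.6,3.10,CH2,2,FALSE
P,Pro Ca-Ha,63.3,4.42,CH,1,FALSE
P,Pro Cd-Hd,49.8,3.63,CH2,2,FALSE
S,Ser Ca-Ha,58.3,4.47,CH,1,FALSE
S,Ser Cb-Hb,63.8,3.87,CH2,2,FALSE
T,Thr Ca-Ha,61.8,4.35,CH,1,FALSE
T,Thr Cb-Hb,69.8,4.24,CH,1,FALSE
W,Trp Ca-Ha,57.5,4.70,CH,1,FALSE
W,Trp Cb-Hb,29.6,3.28,CH2,2,FALSE
Y,Tyr Ca-Ha,57.9,4.55,CH,1,FALSE
Y,Tyr Cb-Hb,38.8,3.02,CH2,2,FALSE
V,Val Ca-Ha,62.2,4.12,CH,1,FALSE
S,Ser(-Pro) Ca-Ha,56.6,4.71,CH,1,TRUE
T,Thr(-Pro) Ca-Ha,60.1,4.60,CH,1,TRUE
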
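# amadori_library v1 — DSS-referenced 1H/13C cross-peak fingerprint of the
# Amadori product (fructoselysine) in denatured proteins.
# beta-pyranose: experimental values (BSA column of the main-form table).
# Minor forms (furanoses, alpha-pyranose): SYNTHETIC placeholder positions,
# kept >= 1 ppm (13C) away from the beta-pyranose diagnostic markers; only
# their populations are literature equilibrium values.
# C2 carries no proton (quaternary after cyclization): hsqc_visible = FALSE.
form,label,c13_ppm,h1_ppm,multiplicity,protons_in_signal,diagnostic,exchange_affected,hsqc_visible,population
beta-pyranose,C1-H1,55.6,3.29,CH2,2,FALSE,TRUE,TRUE,0.70
beta-pyranose,C2,98.2,NA,none,NA,FALSE,FALSE,FALSE,0.70
beta-pyranose,C3-H3,72.4,3.75,CH,1,FALSE,FALSE,TRUE,0.70
beta-pyranose,C4-H4,72.1,3.89,CH,1,FALSE,FALSE,TRUE,0.70
beta-pyranose,C5-H5,71.8,4.00,CH,1,TRUE,FALSE,TRUE,0.70
beta-pyranose,C6-H6,66.7,3.99,CH2,1,TRUE,FALSE,TRUE,0.70
beta-pyranose,C6-H6',66.7,3.76,CH2,1,TRUE,FALSE,TRUE,0.70
beta-pyranose,Lys Ce-He,50.9,3.06,CH2,2,FALSE,FALSE,TRUE,0.70
beta-furanose,C1-H1,54.0,3.35,CH2,2,FALSE,TRUE,TRUE,0.13
beta-furanose,C3-H3,77.5,4.10,CH,1,FALSE,FALSE,TRUE,0.13
beta-furanose,C4-H4,76.0,4.05,CH,1,FALSE,FALSE,TRUE,0.13
beta-furanose,C5-H5,81.5,3.95,CH,1,FALSE,FALSE,TRUE,0.13
beta-furanose,C6-H6,63.5,3.65,CH2,1,FALSE,FALSE,TRUE,0.13
beta-furanose,C6-H6',63.5,3.55,CH2,1,FALSE,FALSE,TRUE,0.13
alpha-furanose,C1-H1,53.0,3.40,CH2,2,FALSE,TRUE,TRUE,0.13
alpha-furanose,C3-H3,82.5,4.15,CH,1,FALSE,FALSE,TRUE,0.13
alpha-furanose,C4-H4,77.0,4.08,CH,1,FALSE,FALSE,TRUE,0.13
alpha-furanose,C5-H5,83.5,4.02,CH,1,FALSE,FALSE,TRUE,0.13
alpha-furanose,C6-H6,62.0,3.70,CH2,1,FALSE,FALSE,TRUE,0.13
alpha-furanose,C6-H6',62.0,3.60,CH2,1,FALSE,FALSE,TRUE,0.13
alpha-pyranose,C1-H1,52.0,3.45,CH2,2,FALSE,TRUE,TRUE,0.04
alpha-pyranose,C3-H3,70.0,3.70,CH,1,FALSE,FALSE,TRUE,0.04
alpha-pyranose,C4-H4,70.6,3.62,CH,1,FALSE,FALSE,TRUE,0.04
alpha-pyranose,C5-H5,69.3,4.06,CH,1,FALSE,FALSE,TRUE,0.04
alpha-pyranose,C6-H6,64.4,3.84,CH2,1,FALSE,FALSE,TRUE,0.04
alpha-pyranose,C6-H6',64.4,3.68,CH2,1,FALSE,FALSE,TRUE,0.04
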
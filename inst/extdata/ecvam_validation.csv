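chemical,abbreviation,sum_abc,animal_label,limb_flag
all-trans-Retinoic acid,ATRA,65.85,P,TRUE
Hydroxyurea,HU,63.29,P,TRUE
Methoxyacetic acid,MAA,225.30,P,TRUE
Methylmercury chloride,MeHg,77.73,P,TRUE
Methotrexate hydrate,MTX,80.48,P,TRUE
Sodium salicylate,SA,38.69,P,TRUE
Valproic acid,VPA,91.74,P,TRUE
6-Aminonicotinamide,6-AN,24.88,P,FALSE
Boric acid,BA,24.18,P,FALSE
5-Bromo-2'-deoxyuridine,BrdU,83.91,P,FALSE
"5,5-Dimethyl-2,4-oxazolidinedione",DMO,50.29,P,FALSE
Lithium chloride,LiCl,29.75,P,FALSE
Acrylamide,AcA,37.09,N,FALSE
D-Camphor,CAM,27.48,N,FALSE
Diphenhydramine hydrochloride,DHM,68.18,N,FALSE
Dimethyl phthalate,DMP,24.41,N,FALSE
Penicillin G sodium salt,PenG,22.12,N,FALSE
Sodium saccharin,SAC,33.99,N,FALSE
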
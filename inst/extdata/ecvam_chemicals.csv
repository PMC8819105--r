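chemical,abbreviation,cas,vehicle,max_conc_ug_ml,animal_label
all-trans-Retinoic acid,ATRA,302-79-4,DMSO,0.010,P
Hydroxyurea,HU,127-07-1,PBS,149,P
Methoxyacetic acid,MAA,625-45-6,PBS,683,P
Methylmercury chloride,MeHg,115-09-3,DMSO,1.20,P
Methotrexate hydrate,MTX,133073-73-1,DMSO,5.00,P
Sodium salicylate,SA,54-21-7,PBS,666,P
Valproic acid,VPA,99-66-1,DMSO,100,P
6-Aminonicotinamide,6-AN,329-89-5,DMSO,1.00,P
Boric acid,BA,10043-35-3,PBS,250,P
5-Bromo-2'-deoxyuridine,BrdU,59-14-3,DMSO,50.0,P
"5,5-Dimethyl-2,4-oxazolidinedione",DMO,695-53-4,PBS,840,P
Lithium chloride,LiCl,7447-41-8,PBS,250,P
Acrylamide,AcA,79-06-1,PBS,454,N
D-Camphor,CAM,464-49-3,DMSO,50.0,N
Diphenhydramine hydrochloride,DHM,147-24-0,PBS,262,N
Dimethyl phthalate,DMP,131-11-3,DMSO,100,N
Penicillin G sodium salt,PenG,69-57-8,PBS,1000,N
Sodium saccharin,SAC,82385-42-0,PBS,1000,N
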
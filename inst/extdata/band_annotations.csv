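wavenumber,category,description
620,nucleic_acid,guanine ring deformation
645,protein,tyrosine skeletal deformation
666,nucleic_acid,guanine/thymine ring breathing
678,nucleic_acid,guanine ring vibration
720,nucleic_acid,adenine ring breathing
728,nucleic_acid,adenine ring vibration
760,protein,tryptophan ring breathing
782,nucleic_acid,"cytosine, uracil ring stretching (DNA/RNA)"
811,nucleic_acid,RNA O-P-O backbone stretching
823,nucleic_acid,DNA O-P-O backbone stretching
830,protein,tyrosine Fermi doublet
853,protein,tyrosine ring breathing
898,carbohydrate,C-O-C skeletal stretching
937,protein,C-C backbone stretching (alpha helix)
957,lipid,CH3 deformation / C=C lipid
1002,protein,phenylalanine symmetric ring breathing
1033,protein,phenylalanine C-H in-plane bending
1046,carbohydrate,C-O / C-C stretching (polysaccharide)
1064,lipid,C-C skeletal stretching (trans chain)
1092,nucleic_acid,PO2- symmetric stretching (DNA backbone)
1103,carbohydrate,C-O stretching (glycosidic)
1127,lipid,C-C stretching of saturated lipid chains
1157,carbohydrate,C-C / C-O ring stretching
1174,protein,tyrosine C-H in-plane bending
1209,protein,phenylalanine / tryptophan C-C6H5 stretching
1230,nucleic_acid,thymine ring / antisymmetric phosphate
1242,protein,amide III (beta sheet)
1263,lipid,=C-H in-plane deformation (cis unsaturated)
1302,protein,amide III / CH2 twisting
1308,protein,CH3/CH2 twisting of protein side chains
1320,nucleic_acid,guanine C-H deformation
1340,nucleic_acid,adenine / CH deformation
1380,carbohydrate,CH3 symmetric bending (polysaccharide)
1400,protein,COO- symmetric stretching
1445,lipid,alkyl C-H2 bending (total lipids)
1448,lipid,CH2 deformation (lipid)
1481,nucleic_acid,"guanine, adenine ring stretching"
1523,carbohydrate,C=C conjugated stretching
1555,protein,amide II / tryptophan
1575,nucleic_acid,"guanine, adenine ring vibration"
1605,protein,phenylalanine ring C=C stretching
1620,protein,C=C stretching of tyrosine/tryptophan
1658,lipid,C=C stretching of unsaturated fatty acids
1661,lipid,cis C=C stretching (membrane lipid)
1735,lipid,C=O ester stretching (phospholipid)
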
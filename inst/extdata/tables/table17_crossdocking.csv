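target,drug,affinity,cnn_pose_score,cnn_affinity,rmsd
VEGFR-2 (PDB ID:4ASE),Axitinib,-8.53,0.842,7.634,5.500
VEGFR-2 (PDB ID:4ASE),Cabozatinib,-11.86,0.913,7.725,1.059
VEGFR-2 (PDB ID:4ASE),Fruquitinib,-8.74,0.906,7.672,1.499
VEGFR-2 (PDB ID:4ASE),Lenvatinib,-11.03,0.957,8.049,2.776
VEGFR-2 (PDB ID:4ASE),Pazopanib,-8.69,0.856,7.407,3.730
VEGFR-2 (PDB ID:4ASE),Regorafenib,-11.24,0.890,7.833,1.688
VEGFR-2 (PDB ID:4ASE),Sorafenib,-11.25,0.882,7.588,2.536
VEGFR-2 (PDB ID:4ASE),Sunitinib,-7.35,0.728,7.312,5.250
VEGFR-2 (PDB ID:4ASE),Vandetanib,-10.42,0.814,8.062,1.514
HER2 (PDB ID:7PCD),Afatinib,-7.61,0.925,7.381,2.906
HER2 (PDB ID:7PCD),Capivasertib,-9.71,0.898,7.45,2.537
HER2 (PDB ID:7PCD),Lapatinib,-9.98,0.858,7.609,2.022
HER2 (PDB ID:7PCD),Neratinib,-7.51,0.780,7.875,2.432
HER2 (PDB ID:7PCD),Tucatinib,-10.64,0.750,7.634,1.494
EGFR (PDB ID:7T4I),Afatinib,-8.35,0.900,7.852,2.169
EGFR (PDB ID:7T4I),Dacomitinib,-8.60,0.932,8.125,2.186
EGFR (PDB ID:7T4I),Gefitinib,-7.93,0.983,7.986,1.862
EGFR (PDB ID:7T4I),Osimertinib,-7.12,0.932,7.948,1.562
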
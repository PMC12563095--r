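id,lipinski,ghose,veber,egan,muegge,mddr_like,qed,score
Filgotinib,pass,pass,pass,pass,pass,pass,0.671,6.671
Sunitinib,pass,pass,pass,pass,pass,pass,0.626,6.626
Fruquintinib,pass,pass,pass,pass,pass,pass,0.55,6.550
Lenvatinib,pass,pass,pass,pass,pass,pass,0.549,6.549
Vandetanib,pass,pass,pass,pass,pass,pass,0.542,6.542
Axitinib,pass,pass,pass,pass,pass,pass,0.524,6.524
Gefitinib,pass,pass,pass,pass,pass,pass,0.518,6.518
Asciminib,pass,pass,pass,pass,pass,pass,0.498,6.498
Capivasertib,pass,pass,pass,pass,pass,pass,0.477,6.477
Pexidartinib,pass,pass,pass,pass,pass,pass,0.466,6.466
Pirtobrutinib,pass,pass,pass,pass,pass,pass,0.448,6.448
Erlotinib,pass,pass,pass,pass,pass,pass,0.418,6.418
Tivozanib,pass,pass,pass,pass,pass,pass,0.388,6.388
Momelotinib,pass,pass,pass,pass,pass,pass,0.598,6.598
Tofacitinib,pass,pass,pass,pass,pass,mid-structure,0.928,5.928
Ritlecitinib,pass,pass,pass,pass,pass,mid-structure,0.845,5.845
Abrocitinib,pass,pass,pass,pass,pass,mid-structure,0.835,5.835
Ruxolitinib,pass,pass,pass,pass,pass,mid-structure,0.8,5.800
Upadacitinib,pass,pass,pass,pass,pass,mid-structure,0.733,5.733
Baricitinib,pass,pass,pass,pass,pass,mid-structure,0.717,5.717
Larotrectinib,pass,pass,pass,pass,pass,mid-structure,0.67,5.670
Repotrectinib,pass,pass,pass,pass,pass,mid-structure,0.648,5.648
Lorlatinib,pass,pass,pass,pass,pass,mid-structure,0.615,5.615
Pemigatinib,pass,fail,pass,pass,pass,pass,0.572,5.572
Crizotinib,pass,pass,pass,pass,pass,mid-structure,0.533,5.533
Zanubrutinib,pass,fail,pass,pass,pass,pass,0.524,5.524
Futibatinib,pass,pass,pass,pass,pass,mid-structure,0.508,5.508
Deucravacitinib,pass,pass,pass,fail,pass,pass,0.496,5.496
Pazopanib,pass,pass,pass,pass,pass,mid-structure,0.492,5.492
Capmatinib,pass,pass,pass,pass,pass,mid-structure,0.489,5.489
Ibrutinib,pass,fail,pass,pass,pass,pass,0.467,5.467
Dasatinib,pass,fail,pass,pass,pass,pass,0.466,5.466
Dacomitinib,pass,fail,pass,pass,pass,pass,0.465,5.465
Afatinib,pass,fail,pass,pass,pass,pass,0.457,5.457
Erdafitinib,pass,fail,pass,pass,pass,pass,0.413,5.413
Regorafenib,pass,fail,pass,pass,pass,pass,0.407,5.407
Tepotinib,pass,fail,pass,pass,pass,pass,0.385,5.385
Tucatinib,pass,fail,pass,pass,pass,pass,0.358,5.358
Gilteritinib,1 violation,fail,pass,pass,pass,pass,0.428,4.928
Bosutinib,1 violation,fail,pass,pass,pass,pass,0.379,4.879
Selpercatinib,1 violation,fail,pass,pass,pass,pass,0.37,4.870
Brigatinib,1 violation,fail,pass,pass,pass,pass,0.352,4.852
Nintedanib,1 violation,fail,pass,pass,pass,pass,0.35,4.850
Cabozantinib,1 violation,fail,pass,pass,pass,pass,0.308,4.808
Pralsetinib,1 violation,fail,pass,pass,pass,pass,0.307,4.807
Pacritinib,pass,fail,pass,pass,pass,mid-structure,0.538,4.538
Acalabrutinib,pass,fail,pass,pass,pass,mid-structure,0.447,4.447
Avapritinib,pass,fail,pass,pass,pass,mid-structure,0.394,4.394
Osimertinib,pass,fail,fail,pass,pass,pass,0.311,4.311
Ponatinib,1 violation,fail,pass,pass,pass,mid-structure,0.394,3.894
Neratinib,1 violation,fail,fail,pass,pass,pass,0.218,3.718
Mobocertinib,1 violation,fail,fail,pass,pass,pass,0.174,3.674
Infigratinib,fail,fail,pass,pass,fail,pass,0.381,3.381
Ripretinib,fail,fail,pass,pass,fail,pass,0.323,3.323
Entrectinib,fail,fail,pass,pass,fail,pass,0.294,3.294
Ceritinib,fail,fail,pass,pass,fail,pass,0.279,3.279
Nilotinib,fail,fail,pass,pass,fail,pass,0.266,3.266
Alectinib,1 violation,fail,pass,pass,fail,mid-structure,0.582,3.082
Midostaurin,1 violation,fail,pass,pass,fail,mid-structure,0.287,2.787
Fedratinib,fail,fail,fail,pass,fail,pass,0.346,2.346
Quizatinib,fail,fail,pass,fail,fail,pass,0.257,2.257
Lapatinib,fail,fail,fail,pass,fail,pass,0.179,2.179
Fostamatinib,fail,fail,fail,fail,fail,pass,0.256,1.256
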
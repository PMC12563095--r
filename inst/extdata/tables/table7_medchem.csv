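id,leadlikeness,gsk,pains,brenk,score
Abrocitinib,pass,pass,pass,pass,4
Ruxolitinib,pass,pass,pass,pass,4
Tofacitinib,pass,pass,pass,pass,4
Baricitinib,fail,pass,pass,pass,3
Fruquintinib,fail,pass,pass,pass,3
Repotrectinib,fail,pass,pass,pass,3
Ritlecitinib,pass,pass,pass,fail,3
Upadacitinib,fail,pass,pass,pass,3
Alectinib,fail,fail,pass,pass,2
Avapritinib,fail,fail,pass,pass,2
Axitinib,fail,fail,pass,pass,2
Bosutinib,fail,fail,pass,pass,2
Capivasertib,fail,fail,pass,pass,2
Capmatinib,fail,fail,pass,pass,2
Ceritinib,fail,fail,pass,pass,2
Dasatinib,fail,fail,pass,pass,2
Deucravacitinib,fail,fail,pass,pass,2
Entrectinib,fail,fail,pass,pass,2
Erdafitinib,fail,fail,pass,pass,2
Erlotinib,fail,pass,pass,fail,2
Fedratinib,fail,fail,pass,pass,2
Filgotinib,fail,fail,pass,pass,2
Gefitinib,fail,fail,pass,pass,2
Lapatinib,fail,fail,pass,pass,2
Larotrectinib,fail,fail,pass,pass,2
Lenvatinib,fail,fail,pass,pass,2
Lorlatinib,fail,fail,pass,pass,2
Midostaurin,fail,fail,pass,pass,2
Nilotinib,fail,fail,pass,pass,2
Pazopanib,fail,fail,pass,pass,2
Pemigatinib,fail,fail,pass,pass,2
Pexidartinib,fail,fail,pass,pass,2
Pirtobrutinib,fail,fail,pass,pass,2
Pralsetinib,fail,fail,pass,pass,2
Quizatinib,fail,fail,pass,pass,2
Regorafenib,fail,fail,pass,pass,2
Ripretinib,fail,fail,pass,pass,2
Selpercatinib,fail,fail,pass,pass,2
Sunitinib,fail,pass,pass,fail,2
Tepotinib,fail,fail,pass,pass,2
Tivozanib,fail,fail,pass,pass,2
Tucatinib,fail,fail,pass,pass,2
Vandetanib,fail,fail,pass,pass,2
Acalabrutinib,fail,fail,pass,fail,1
Afatinib,fail,fail,pass,fail,1
Asciminib,fail,fail,pass,fail,1
Brigatinib,fail,fail,pass,fail,1
Cabozantinib,fail,fail,pass,fail,1
Crizotinib,fail,fail,pass,fail,1
Dacomitinib,fail,fail,pass,fail,1
Fostamatinib,fail,fail,pass,fail,1
Futibatinib,fail,fail,pass,fail,1
Gilteritinib,fail,fail,fail,pass,1
Ibrutinib,fail,fail,pass,fail,1
Infigratinib,fail,fail,fail,pass,1
Mobocertinib,fail,fail,pass,fail,1
Neratinib,fail,fail,pass,fail,1
Nintedanib,fail,fail,pass,fail,1
Osimertinib,fail,fail,pass,fail,1
Pacritinib,fail,fail,pass,fail,1
Ponatinib,fail,fail,pass,fail,1
Zanubrutinib,fail,fail,pass,fail,1
Momelotinib,fail,fail,fail,fail,0
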
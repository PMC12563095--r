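id,bioavailability_exp,bioavailability_pred,ppb_exp,ppb_pred,clearance_exp,clearance_pred,ames_exp,ames_pred,carcinogenicity_exp,carcinogenicity_pred,herg_exp,herg_pred,hepatotoxicity_exp,hepatotoxicity_pred
Abrocitinib,high,high,low,low,*,high,negative,negative,negative,negative,*,negative,negative,positive
Acalabrutinib,low,high,high,high,high,low,*,positive,negative,negative,*,positive,positive,negative
Afatinib,high,low,high,high,high,low,*,positive,*,negative,*,positive,positive,positive
Alectinib,low,low,high,high,high,high,negative,negative,*,positive,*,positive,positive,negative
Asciminib,*,low,high,high,low,low,negative,positive,*,positive,*,positive,negative,negative
Avapritinib,high,low,high,low,low,high,negative,negative,*,positive,*,positive,negative,negative
Axitinib,high,high,high,high,low,low,positive,positive,*,negative,negative,negative,positive,positive
Baricitinib,high,high,low,low,low,high,negative,negative,negative,negative,*,negative,negative,negative
Bosutinib,low,low,high,high,high,low,negative,negative,negative,negative,negative,positive,positive,negative
Brigatinib,low,high,low,low,low,low,negative,negative,*,negative,*,negative,positive,negative
Cabozantinib,high,high,high,high,low,low,negative,negative,negative,positive,*,positive,positive,positive
Capivasertib,low,low,low,low,low,low,*,negative,negative,negative,*,positive,negative,negative
Capmatinib,high,high,high,high,low,low,*,positive,negative,positive,*,positive,positive,negative
Ceritinib,*,high,high,high,low,low,negative,negative,*,negative,*,positive,positive,positive
Crizotinib,low,high,high,low,high,low,negative,positive,*,negative,positive,positive,positive,negative
Dacomitinib,high,high,high,high,low,high,negative,negative,*,negative,*,positive,negative,negative
Dasatinib,high,low,high,high,high,low,negative,negative,positive,negative,negative,negative,positive,negative
Deucravacitinib,high,high,low,low,low,low,negative,negative,negative,negative,*,negative,negative,positive
Entrectinib,*,low,high,high,low,low,negative,negative,*,negative,*,positive,positive,negative
Erdafitinib,high,low,high,low,low,low,negative,negative,*,positive,*,positive,negative,negative
Erlotinib,high,high,high,high,low,low,negative,positive,positive,positive,negative,positive,positive,negative
Fedratinib,*,high,high,high,low,low,negative,negative,negative,negative,*,positive,positive,positive
Filgotinib,*,high,*,low,*,low,*,negative,*,positive,*,negative,*,negative
Fostamatinib,high,high,high,high,*,low,negative,negative,negative,negative,*,negative,positive,positive
Fruquintinib,*,high,high,low,low,low,negative,positive,*,positive,*,negative,positive,positive
Futibatinib,*,high,high,low,low,low,negative,positive,*,negative,*,positive,negative,negative
Gefitinib,high,high,low,low,*,low,negative,positive,positive,negative,positive,positive,positive,negative
Gilteritinib,*,low,high,low,low,high,negative,positive,*,positive,*,positive,negative,negative
Ibrutinib,low,low,high,high,high,low,negative,positive,negative,positive,*,positive,positive,positive
Infigratinib,*,high,high,high,low,low,negative,negative,*,negative,*,positive,negative,positive
Lapatinib,*,low,high,high,*,low,negative,positive,negative,negative,positive,negative,positive,positive
Larotrectinib,low,high,low,low,high,low,negative,positive,*,positive,*,negative,positive,positive
Lenvatinib,high,low,high,high,*,low,negative,positive,*,positive,*,positive,positive,negative
Lorlatinib,high,high,low,high,low,low,negative,positive,*,positive,*,negative,positive,negative
Midostaurin,*,low,high,high,*,low,negative,negative,*,positive,*,positive,negative,negative
Mobocertinib,low,low,high,low,high,low,negative,negative,*,positive,*,positive,negative,positive
Momelotinib,*,high,high,high,high,low,negative,positive,negative,positive,*,negative,positive,positive
Neratinib,high,low,high,high,high,low,negative,negative,negative,negative,*,positive,positive,negative
Nilotinib,low,high,high,high,low,low,negative,negative,negative,negative,positive,positive,positive,negative
Nintedanib,low,low,high,low,high,low,negative,negative,negative,negative,*,positive,positive,positive
Osimertinib,low,low,high,high,low,low,negative,positive,positive,positive,*,positive,*,positive
Pacritinib,*,high,high,low,low,low,negative,negative,negative,positive,*,positive,negative,positive
Pazopanib,low,low,high,high,*,low,negative,negative,positive,positive,negative,negative,positive,positive
Pemigatinib,low,high,high,low,low,high,negative,negative,*,positive,*,negative,negative,negative
Pexidartinib,*,high,high,high,low,high,negative,negative,negative,negative,*,positive,negative,positive
Pirtobrutinib,high,high,high,high,low,low,negative,positive,*,positive,*,positive,positive,negative
Ponatinib,*,high,high,high,*,low,negative,negative,positive,negative,*,positive,negative,negative
Pralsetinib,*,high,high,high,low,low,negative,negative,*,positive,*,positive,positive,positive
Quizatinib,*,high,*,high,*,low,*,negative,*,positive,*,positive,*,negative
Regorafenib,high,low,high,high,*,low,*,negative,*,negative,negative,negative,positive,positive
Repotrectinib,low,low,high,low,low,low,negative,positive,*,positive,*,positive,positive,positive
Ripretinib,high,high,high,high,low,low,negative,positive,*,positive,*,negative,negative,positive
Ritlecitinib,high,high,low,low,*,low,negative,positive,positive,positive,*,negative,negative,positive
Ruxolitinib,high,high,high,low,low,high,negative,negative,negative,positive,negative,negative,negative,negative
Selpercatinib,high,low,high,high,low,low,negative,positive,negative,negative,*,negative,positive,negative
Sunitinib,high,high,high,low,low,high,negative,positive,positive,positive,positive,positive,positive,positive
Tepotinib,high,high,high,high,low,high,*,negative,*,negative,*,positive,positive,negative
Tivozanib,high,high,high,high,low,low,*,negative,*,positive,*,positive,negative,positive
Tofacitinib,high,high,low,low,*,high,negative,negative,negative,negative,*,negative,negative,negative
Tucatinib,*,high,high,high,high,low,negative,negative,*,positive,*,positive,positive,positive
Upadacitinib,*,low,low,low,*,low,negative,negative,negative,positive,*,negative,negative,negative
Vandetanib,high,high,high,low,*,high,negative,negative,*,positive,positive,positive,negative,negative
Zanubrutinib,*,low,high,low,high,low,negative,positive,*,negative,*,positive,positive,negative
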
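id,clearance
Abrocitinib,high
Acalabrutinib,low
Afatinib,low
Alectinib,high
Asciminib,low
Avapritinib,high
Axitinib,low
Baricitinib,high
Bosutinib,low
Brigatinib,low
Cabozantinib,low
Capmatinib,low
Capivasertib,low
Ceritinib,low
Crizotinib,low
Dacomitinib,high
Dasatinib,low
Deucravacitinib,low
Entrectinib,low
Erdafitinib,low
Erlotinib,low
Fedratinib,low
Filgotinib,low
Fostamatinib,low
Fruquintinib,low
Futibatinib,low
Gefitinib,low
Gilteritinib,high
Ibrutinib,low
Infigratinib,low
Lapatinib,low
Larotrectinib,low
Lenvatinib,low
Lorlatinib,low
Midostaurin,low
Mobocertinib,low
Momelotinib,low
Neratinib,low
Nilotinib,low
Nintedanib,low
Osimertinib,low
Pacritinib,low
Pazopanib,low
Pemigatinib,high
Pexidartinib,high
Pirtobrutinib,low
Ponatinib,low
Pralsetinib,low
Quizatinib,low
Regorafenib,low
Repotrectinib,low
Ripretinib,low
Ritlecitinib,low
Ruxolitinib,high
Selpercatinib,low
Sunitinib,high
Tepotinib,high
Tivozanib,low
Tofacitinib,high
Tucatinib,low
Upadacitinib,low
Vandetanib,high
Zanubrutinib,low
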
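id,ppb
Abrocitinib,low
Avapritinib,low
Baricitinib,low
Brigatinib,low
Capivasertib,low
Crizotinib,low
Deucravacitinib,low
Erdafitinib,low
Filgotinib,low
Fruquintinib,low
Futibatinib,low
Gefitinib,low
Gilteritinib,low
Larotrectinib,low
Mobocertinib,low
Nintedanib,low
Pacritinib,low
Pemigatinib,low
Repotrectinib,low
Ritlecitinib,low
Ruxolitinib,low
Sunitinib,low
Tofacitinib,low
Upadacitinib,low
Vandetanib,low
Zanubrutinib,low
Acalabrutinib,high
Afatinib,high
Alectinib,high
Asciminib,high
Axitinib,high
Bosutinib,high
Cabozantinib,high
Capmatinib,high
Ceritinib,high
Dacomitinib,high
Dasatinib,high
Entrectinib,high
Erlotinib,high
Fedratinib,high
Fostamatinib,high
Ibrutinib,high
Infigratinib,high
Lapatinib,high
Lenvatinib,high
Lorlatinib,high
Midostaurin,high
Momelotinib,high
Neratinib,high
Nilotinib,high
Osimertinib,high
Pazopanib,high
Pexidartinib,high
Pirtobrutinib,high
Ponatinib,high
Pralsetinib,high
Quizatinib,high
Regorafenib,high
Ripretinib,high
Selpercatinib,high
Tepotinib,high
Tivozanib,high
Tucatinib,high
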
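id,ames,carcinogenicity,herg,hepatotoxicity,score
Baricitinib,negative,negative,inactive,negative,4
Brigatinib,negative,negative,inactive,negative,4
Dasatinib,negative,negative,inactive,negative,4
Tofacitinib,negative,negative,inactive,negative,4
Abrocitinib,negative,negative,inactive,positive,3
Bosutinib,negative,negative,active,negative,3
Capivasertib,negative,negative,active,negative,3
Dacomitinib,negative,negative,active,negative,3
Deucravacitinib,negative,negative,inactive,positive,3
Entrectinib,negative,negative,active,negative,3
Filgotinib,negative,positive,inactive,negative,3
Fostamatinib,negative,negative,inactive,positive,3
Neratinib,negative,negative,active,negative,3
Nilotinib,negative,negative,active,negative,3
Pemigatinib,negative,positive,inactive,negative,3
Ponatinib,negative,negative,active,negative,3
Regorafenib,negative,negative,inactive,positive,3
Ruxolitinib,negative,positive,inactive,negative,3
Selpercatinib,positive,negative,inactive,negative,3
Tepotinib,negative,negative,active,negative,3
Upadacitinib,negative,positive,inactive,negative,3
Acalabrutinib,positive,negative,active,negative,2
Alectinib,negative,positive,active,negative,2
Avapritinib,negative,positive,active,negative,2
Axitinib,positive,negative,inactive,positive,2
Ceritinib,negative,negative,active,positive,2
Crizotinib,positive,negative,active,negative,2
Erdafitinib,negative,positive,active,negative,2
Fedratinib,negative,negative,active,positive,2
Futibatinib,positive,negative,active,negative,2
Gefitinib,positive,negative,active,negative,2
Infigratinib,negative,negative,active,positive,2
Lapatinib,positive,negative,inactive,positive,2
Lorlatinib,positive,positive,inactive,negative,2
Midostaurin,negative,positive,active,negative,2
Nintedanib,negative,negative,active,positive,2
Pazopanib,negative,positive,inactive,positive,2
Pexidartinib,negative,negative,active,positive,2
Quizatinib,negative,positive,active,negative,2
Vandetanib,negative,positive,active,negative,2
Zanubrutinib,positive,negative,active,negative,2
Afatinib,positive,negative,active,positive,1
Asciminib,positive,positive,active,negative,1
Capmatinib,positive,positive,active,negative,1
Erlotinib,positive,positive,active,negative,1
Fruquintinib,positive,positive,inactive,positive,1
Gilteritinib,positive,positive,active,negative,1
Larotrectinib,positive,positive,inactive,positive,1
Lenvatinib,positive,positive,active,negative,1
Mobocertinib,negative,positive,active,positive,1
Momelotinib,positive,positive,inactive,positive,1
Pacritinib,negative,positive,active,positive,1
Pirtobrutinib,positive,positive,active,negative,1
Pralsetinib,negative,positive,active,positive,1
Ripretinib,positive,positive,inactive,positive,1
Ritlecitinib,positive,positive,inactive,positive,1
Tivozanib,negative,positive,active,positive,1
Tucatinib,negative,positive,active,positive,1
Cabozantinib,negative,positive,active,positive,1
Ibrutinib,positive,positive,active,positive,0
Osimertinib,positive,positive,active,positive,0
Repotrectinib,positive,positive,active,positive,0
Sunitinib,positive,positive,active,positive,0
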
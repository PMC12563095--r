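id,caco2,hia,mdck,pgp_substrate,pgp_inhibitor,score,overall
Lorlatinib,high,high,high,no,no,5,high
Ruxolitinib,high,high,high,no,no,5,high
Baricitinib,high,high,moderate,no,no,4.5,high
Ritlecitinib,high,high,moderate,no,no,4.5,high
Abrocitinib,moderate,high,moderate,no,no,4,high
Capmatinib,high,high,high,yes,yes,4,high
Deucravacitinib,moderate,high,moderate,no,no,4,high
Filgotinib,moderate,high,moderate,no,no,4,high
Fruquintinib,high,high,high,no,yes,4,high
Futibatinib,high,high,high,no,yes,4,high
Gefitinib,high,high,high,yes,yes,4,high
Pemigatinib,high,high,high,yes,yes,4,high
Pexidartinib,high,high,high,yes,yes,4,high
Tofacitinib,moderate,high,moderate,no,no,4,high
Vandetanib,high,high,high,yes,yes,4,high
Cabozantinib,moderate,high,high,yes,yes,3.5,high
Erlotinib,high,high,moderate,no,yes,3.5,high
Fostamatinib,moderate,high,low,no,no,3.5,high
Infigratinib,moderate,high,high,yes,yes,3.5,high
Larotrectinib,high,high,moderate,yes,yes,3.5,high
Momelotinib,high,high,moderate,yes,yes,3.5,high
Pirtobrutinib,moderate,high,high,yes,yes,3.5,high
Ripretinib,moderate,high,high,no,yes,3.5,high
Tepotinib,moderate,high,high,yes,yes,3.5,high
Tivozanib,moderate,high,high,no,yes,3.5,high
Acalabrutinib,high,high,low,yes,yes,3,high
Axitinib,high,high,low,yes,yes,3,high
Brigatinib,moderate,high,moderate,yes,yes,3,high
Ceritinib,moderate,high,moderate,yes,yes,3,high
Crizotinib,high,high,low,yes,yes,3,high
Dacomitinib,high,high,low,yes,yes,3,high
Fedratinib,moderate,high,moderate,yes,yes,3,high
Nilotinib,moderate,high,moderate,yes,yes,3,high
Pacritinib,high,high,low,yes,yes,3,high
Ponatinib,moderate,high,moderate,yes,yes,3,high
Pralsetinib,moderate,high,moderate,yes,yes,3,high
Quizatinib,moderate,high,moderate,yes,yes,3,high
Sunitinib,moderate,high,moderate,yes,yes,3,high
Tucatinib,high,high,low,yes,yes,3,high
Afatinib,moderate,high,low,yes,yes,2.5,low
Alectinib,moderate,high,low,yes,yes,2.5,low
Asciminib,moderate,high,low,no,yes,2.5,low
Avapritinib,moderate,high,low,yes,yes,2.5,low
Bosutinib,moderate,high,low,yes,yes,2.5,low
Dasatinib,moderate,high,low,yes,yes,2.5,low
Entrectinib,moderate,high,low,yes,yes,2.5,low
Erdafitinib,moderate,high,low,yes,yes,2.5,low
Gilteritinib,moderate,high,low,yes,yes,2.5,low
Ibrutinib,moderate,high,low,no,yes,2.5,low
Lapatinib,moderate,high,low,yes,yes,2.5,low
Midostaurin,moderate,high,low,yes,yes,2.5,low
Mobocertinib,moderate,high,low,yes,yes,2.5,low
Neratinib,moderate,high,low,yes,yes,2.5,low
Nintedanib,moderate,high,low,yes,yes,2.5,low
Osimertinib,moderate,high,low,yes,yes,2.5,low
Pazopanib,moderate,high,low,no,yes,2.5,low
Regorafenib,moderate,high,low,no,yes,2.5,low
Selpercatinib,moderate,high,low,yes,yes,2.5,low
Upadacitinib,moderate,high,high,yes,no,2.5,low
Zanubrutinib,moderate,high,low,yes,yes,2.5,low
Capivasertib,moderate,high,moderate,yes,no,2,low
Lenvatinib,moderate,high,moderate,yes,no,2,low
Repotrectinib,high,high,low,yes,no,2,low
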
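id,mw_exp,mw_pred,tpsa_exp,tpsa_pred,mr_exp,mr_pred,logp_exp,logp_pred,logp_molinsp_molsoft
Abrocitinib,323.42,323.35,90.98,91.35,86.00,86.59,*,1.56,-
Acalabrutinib,465.52,465.43,118.51,114.06,135.72,136.51,0.49,3.04,2.50
Afatinib,485.94,485.75,88.61,86.09,131.38,129.90,*,3.95,-
Alectinib,482.62,482.54,72.36,69.80,155.11,149.50,*,5.00,-
Asciminib,449.84,449.66,103.37,100.27,104.81,113.26,*,3.20,-
Avapritinib,498.57,498.48,106.29,102.86,164.55,144.37,*,2.58,-
Axitinib,386.47,386.39,70.67,76.06,115.14,112.82,*,4.04,-
Baricitinib,371.42,371.35,120.56,119.33,105.55,98.51,*,0.63,-
Bosutinib,530.45,530.08,82.88,80.03,142.12,150.65,3.34,4.59,4.55
Brigatinib,584.10,583.89,85.86,86.30,164.77,176.58,5.17,4.08,4.53
Cabozantinib,501.51,501.42,98.78,95.78,136.12,136.59,*,4.49,-
Capivasertib,428.92,428.73,120.16,114.08,116.97,118.97,*,1.67,-
Capmatinib,412.43,412.35,85.07,81.96,125.27,113.93,*,2.94,-
Ceritinib,558.14,557.91,105.24,104.90,153.86,158.71,*,5.62,-
Crizotinib,450.34,450.04,77.99,75.79,128.43,120.72,1.83,4.27,3.43
Dacomitinib,469.94,469.75,79.38,77.06,129.91,132.73,3.92,4.96,4.90
Dasatinib,488.01,487.80,106.51,111.29,133.08,138.63,1.80,3.39,3.50
Deucravacitinib,425.47,424.64,135.95,132.40,138.38,113.15,*,1.82,-
Entrectinib,560.65,560.54,85.52,83.34,161.24,163.44,*,4.88,-
Erdafitinib,446.56,446.47,77.33,74.91,139.32,131.48,*,4.00,-
Erlotinib,393.44,393.37,74.73,72.77,107.79,111.40,2.70,2.93,2.50
Fedratinib,524.68,524.58,108.48,108.45,147.88,151.66,*,4.97,-
Filgotinib,425.51,425.42,96.67,96.15,126.12,118.09,*,1.98,-
Fostamatinib,580.46,580.39,186.72,183.88,137.1,141.80,*,2.30,-
Fruquintinib,393.40,393.33,95.71,92.80,106.25,106.77,*,2.92,-
Futibatinib,418.46,418.39,108.39,104.89,122.82,119.66,*,2.22,-
Gefitinib,446.90,446.72,68.74,66.93,117.51,121.66,3.20,4.06,3.82
Gilteritinib,552.72,552.63,121.11,117.42,159.84,168.43,4.35,2.67,3.04
Ibrutinib,440.51,440.43,99.16,95.66,138.07,131.01,3.97,3.85,3.49
Infigratinib,560.48,560.16,95.09,92.08,152.71,159.27,*,4.85,-
Lapatinib,581.06,580.83,106.35,105.71,152.42,153.88,5.40,5.67,5.64
Larotrectinib,428.44,428.38,86,82.90,122.96,117.01,*,2.57,-
Lenvatinib,426.86,426.67,115.57,111.99,112.21,112.86,3.30,3.24,3.14
Lorlatinib,406.42,406.35,110.06,106.65,121.17,111.44,*,2.15,-
Midostaurin,570.65,571.79,77.73,74.48,162.61,169.20,5.89,4.74,4.66
Mobocertinib,585.71,585.61,113.85,110.30,171.52,171.32,*,4.52,-
Momelotinib,414.47,414.39,103.17,100.20,118.46,120.29,*,2.61,-
Neratinib,557.05,556.84,112.4,108.35,157.29,157.05,*,4.80,-
Nilotinib,529.52,529.44,97.62,94.10,152.85,141.08,5.01,5.33,5.14
Nintedanib,539.62,539.54,94.22,92.56,159.1,167.00,3.00,3.17,3.5
Osimertinib,499.62,499.53,87.55,84.72,150.32,150.43,*,3.92,-
Pacritinib,472.59,472.50,68.74,67.92,139.43,143.91,*,4.29,-
Pazopanib,437.52,437.43,119.03,118.07,132.18,121.50,*,3.29,-
Pemigatinib,487.51,487.43,83.16,80.71,125.32,136.22,*,2.99,-
Pexidartinib,417.82,417.64,66.49,63.64,105.89,104.94,*,4.31,-
Pirtobrutinib,479.44,479.36,125.26,121.68,127.89,115.16,*,3.22,-
Ponatinib,532.56,532.48,65.77,63.49,152.63,150.10,*,4.45,-
Pralsetinib,533.61,533.52,135.53,131.05,146.12,143.26,*,3.52,-
Quizatinib,560.67,560.57,106.16,110.87,168.24,160.37,*,5.70,-
Regorafenib,482.82,482.63,92.35,89.51,114.73,112.44,*,5.06,-
Repotrectinib,355.37,355.30,80.55,78.61,106.42,100.58,*,2.28,-
Ripretinib,510.37,510.04,86.36,85.05,133.78,133.19,5.63,4.95,5.29
Ritlecitinib,285.35,285.30,73.91,71.52,82.84,86.07,*,1.52,-
Ruxolitinib,306.37,306.32,83.18,80.38,98.01,87.66,*,2.41,-
Selpercatinib,525.61,525.52,112.04,107.85,158.75,152.98,*,3.35,-
Sunitinib,398.47,398.41,77.23,75.97,116.27,116.31,*,3.00,-
Tepotinib,492.58,492.53,94.71,93.92,154.74,145.45,*,3.95,-
Tivozanib,454.86,454.68,107.74,104.42,120.85,120.00,4.31,4.60,4.28
Tofacitinib,312.37,312.32,88.91,85.66,87.8,91.20,1.81,1.03,0.65
Tucatinib,480.53,480.45,110.85,106.83,148.37,141.66,3.62,4.52,4.46
Upadacitinib,380.38,380.32,78.32,74.97,93.03,96.54,*,2.50,-
Vandetanib,475.35,475.05,59.51,57.76,118.63,123.26,5.00,4.63,4.67
Zanubrutinib,471.56,471.48,102.48,99.64,146.25,141.35,*,3.49,-
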
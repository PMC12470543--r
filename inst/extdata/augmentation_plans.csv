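class,input_count,target,S,R,F
Normocytes,50,1000,1,5,3
Normocytes,50,4000,1,20,3
Hypochromia + 1,50,1000,1,5,3
Hypochromia + 1,50,4000,1,20,3
Hypochromia + 2,50,1000,1,5,3
Hypochromia + 2,50,4000,1,20,3
Hypochromia + 3,50,1000,1,5,3
Hypochromia + 3,50,4000,1,20,3
Hypochromia + 4,25,1000,1,10,3
Hypochromia + 4,25,4000,1,40,3
Basophilic stippling,0,1000,NA,NA,NA
Basophilic stippling,0,4000,NA,NA,NA
HbH inclusions,0,1000,NA,NA,NA
HbH inclusions,0,4000,NA,NA,NA
Diffuse basophilia,0,1000,NA,NA,NA
Diffuse basophilia,0,4000,NA,NA,NA
Cabot ring,0,1000,NA,NA,NA
Cabot ring,0,4000,NA,NA,NA
Hb H,0,1000,NA,NA,NA
Hb H,0,4000,NA,NA,NA
Hb C crystal,0,1000,NA,NA,NA
Hb C crystal,0,4000,NA,NA,NA
Hb SC crystal,0,1000,NA,NA,NA
Hb SC crystal,0,4000,NA,NA,NA
Heinz bodies,2,1000,1,125,3
Heinz bodies,2,4000,2,250,3
Howell-Jolly bodies,25,1000,1,10,3
Howell-Jolly bodies,25,4000,1,40,3
Pappenheimer bodies,10,1000,1,25,3
Pappenheimer bodies,10,4000,1,100,3
Codocytes-01,250,1000,1,1,3
Codocytes-01,250,4000,1,4,3
Codocytes-02,250,1000,1,1,3
Codocytes-02,250,4000,1,4,3
Eccentrocytes,125,1000,1,2,3
Eccentrocytes,125,4000,1,4,3
Spherocytes-01,250,1000,1,1,3
Spherocytes-01,250,4000,1,4,3
Spherocytes-02,250,1000,1,1,3
Spherocytes-02,250,4000,1,4,3
Stomatocytes,50,1000,1,5,3
Stomatocytes,50,4000,1,20,3
Acanthocytes,10,1000,1,25,3
Acanthocytes,10,4000,1,100,3
Dacrocytes,50,1000,1,5,3
Dacrocytes,50,4000,1,20,3
Degmacytes,25,1000,1,10,3
Degmacytes,25,4000,1,40,3
Drepanocytes,25,1000,1,10,3
Drepanocytes,25,4000,1,40,3
Echinocytes,25,1000,1,10,3
Echinocytes,25,4000,1,40,3
Elliptocytes,50,1000,1,5,3
Elliptocytes,50,4000,1,20,3
Keratocytes,5,1000,1,50,3
Keratocytes,5,4000,1,200,3
Knizocytes,125,1000,1,2,3
Knizocytes,125,4000,1,4,3
Ovalocytes,125,1000,1,2,3
Ovalocytes,125,4000,1,4,3
Pyknocytes,125,1000,1,2,3
Pyknocytes,125,4000,1,4,3
Schistocytes,125,1000,1,2,3
Schistocytes,125,4000,1,4,3
Basophil,0,1000,NA,NA,NA
Basophil,0,4000,NA,NA,NA
Eosinophil,0,1000,NA,NA,NA
Eosinophil,0,4000,NA,NA,NA
Lymphocyte,25,1000,1,10,3
Lymphocyte,25,4000,1,40,3
Monocyte,2,1000,1,125,3
Monocyte,2,4000,2,250,3
Neutrophil,10,1000,1,25,3
Neutrophil,10,4000,1,100,3
Platelets-01,50,1000,1,5,3
Platelets-01,50,4000,1,20,3
Platelets-02,50,1000,1,5,3
Platelets-02,50,4000,1,20,3
Large-01,250,1000,1,1,3
Large-01,250,4000,1,4,3
Large-02,250,1000,1,1,3
Large-02,250,4000,1,4,3
Small,50,1000,1,5,3
Small,50,4000,1,20,3
Other,250,1000,1,1,3
Other,250,4000,1,4,3
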
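family,class_name,count,percentage,ellipse_refined
Normocytes,Normocytes,805,5.75,TRUE
Alteration in staining,Hypochromia + 1,1698,12.13,TRUE
Alteration in staining,Hypochromia + 2,1059,7.56,TRUE
Alteration in staining,Hypochromia + 3,240,1.71,TRUE
Alteration in staining,Hypochromia + 4,47,0.34,TRUE
Erythrocyte inclusions,Basophilic stippling,1,0.01,FALSE
Erythrocyte inclusions,HbH inclusions,0,0.00,FALSE
Erythrocyte inclusions,Diffuse basophilia,0,0.00,FALSE
Erythrocyte inclusions,Cabot ring,0,0.00,FALSE
Erythrocyte inclusions,Hb H,0,0.00,FALSE
Erythrocyte inclusions,Hb C crystal,0,0.00,FALSE
Erythrocyte inclusions,Hb SC crystal,0,0.00,FALSE
Erythrocyte inclusions,Heinz bodies,2,0.01,FALSE
Erythrocyte inclusions,Howell-Jolly bodies,47,0.34,FALSE
Erythrocyte inclusions,Pappenheimer bodies,16,0.11,FALSE
Variations in Hb distribution,Codocytes-01,1024,7.31,TRUE
Variations in Hb distribution,Codocytes-02,1050,7.50,TRUE
Variations in Hb distribution,Eccentrocytes,202,1.44,FALSE
Variations in Hb distribution,Spherocytes-01,1718,12.27,TRUE
Variations in Hb distribution,Spherocytes-02,1205,8.61,TRUE
Variations in Hb distribution,Stomatocytes,173,1.24,FALSE
Variations in RBCs shape,Acanthocytes,16,0.11,FALSE
Variations in RBCs shape,Dacrocytes,396,2.83,FALSE
Variations in RBCs shape,Degmacytes,393,2.81,FALSE
Variations in RBCs shape,Drepanocytes,25,0.18,FALSE
Variations in RBCs shape,Echinocytes,27,0.19,FALSE
Variations in RBCs shape,Elliptocytes,136,0.97,TRUE
Variations in RBCs shape,Keratocytes,7,0.05,FALSE
Variations in RBCs shape,Knizocytes,525,3.75,FALSE
Variations in RBCs shape,Ovalocytes,0,0.00,TRUE
Variations in RBCs shape,Pyknocytes,603,4.31,FALSE
Variations in RBCs shape,Schistocytes,488,3.49,FALSE
Leukocytes,Basophil,1,0.01,FALSE
Leukocytes,Eosinophil,0,0.00,FALSE
Leukocytes,Lymphocyte,21,0.15,FALSE
Leukocytes,Monocyte,2,0.01,FALSE
Leukocytes,Neutrophil,9,0.06,FALSE
Platelets,Platelets-01,312,2.23,TRUE
Platelets,Platelets-02,61,0.44,TRUE
Others,Large-01,766,5.47,TRUE
Others,Large-02,537,3.84,TRUE
Others,Small,117,0.84,FALSE
Others,Other,271,1.94,FALSE
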
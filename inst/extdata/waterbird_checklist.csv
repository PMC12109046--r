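species,genus,family,order,guild,iucn_status,protected
Calidris tenuirostris,Calidris,Scolopacidae,Charadriiformes,small_wader,EN,FALSE
Calidris temminckii,Calidris,Scolopacidae,Charadriiformes,small_wader,LC,FALSE
Gallinago gallinago,Gallinago,Scolopacidae,Charadriiformes,small_wader,LC,FALSE
Limosa limosa,Limosa,Scolopacidae,Charadriiformes,small_wader,NT,FALSE
Tringa ochropus,Tringa,Scolopacidae,Charadriiformes,small_wader,LC,FALSE
Tringa glareola,Tringa,Scolopacidae,Charadriiformes,small_wader,LC,FALSE
Tringa totanus,Tringa,Scolopacidae,Charadriiformes,small_wader,LC,FALSE
Actitis hypoleucos,Actitis,Scolopacidae,Charadriiformes,small_wader,LC,FALSE
Charadrius dubius,Charadrius,Charadriidae,Charadriiformes,small_wader,LC,FALSE
Charadrius veredus,Charadrius,Charadriidae,Charadriiformes,small_wader,LC,FALSE
Pluvialis fulva,Pluvialis,Charadriidae,Charadriiformes,small_wader,LC,FALSE
Vanellus cinereus,Vanellus,Charadriidae,Charadriiformes,small_wader,LC,FALSE
Himantopus himantopus,Himantopus,Recurvirostridae,Charadriiformes,small_wader,LC,FALSE
Ardea cinerea,Ardea,Ardeidae,Pelecaniformes,large_wader,LC,FALSE
Ardea purpurea,Ardea,Ardeidae,Pelecaniformes,large_wader,LC,FALSE
Egretta garzetta,Egretta,Ardeidae,Pelecaniformes,large_wader,LC,FALSE
Mesophoyx intermedia,Mesophoyx,Ardeidae,Pelecaniformes,large_wader,LC,FALSE
Bubulcus ibis,Bubulcus,Ardeidae,Pelecaniformes,large_wader,LC,FALSE
Ixobrychus cinnamomeus,Ixobrychus,Ardeidae,Pelecaniformes,large_wader,LC,TRUE
Casmerodius albus,Casmerodius,Ardeidae,Pelecaniformes,large_wader,LC,FALSE
Nycticorax nycticorax,Nycticorax,Ardeidae,Pelecaniformes,large_wader,LC,FALSE
Ardeola grayii,Ardeola,Ardeidae,Pelecaniformes,large_wader,LC,FALSE
Platalea minor,Platalea,Threskiornithidae,Pelecaniformes,large_wader,EN,FALSE
Threskiornis melanocephalus,Threskiornis,Threskiornithidae,Pelecaniformes,large_wader,LC,FALSE
Pelecanus philippensis,Pelecanus,Pelecanidae,Pelecaniformes,large_wader,NT,TRUE
Anas acuta,Anas,Anatidae,Anseriformes,dabbling,LC,TRUE
Anas crecca,Anas,Anatidae,Anseriformes,dabbling,LC,TRUE
Anas querquedula,Anas,Anatidae,Anseriformes,dabbling,LC,TRUE
Anas luzonica,Anas,Anatidae,Anseriformes,dabbling,VU,FALSE
Dendrocygna javanica,Dendrocygna,Anatidae,Anseriformes,dabbling,LC,TRUE
Nettapus coromandelianus,Nettapus,Anatidae,Anseriformes,dabbling,LC,TRUE
Tadorna ferruginea,Tadorna,Anatidae,Anseriformes,dabbling,LC,TRUE
Grus vipio,Grus,Gruidae,Gruiformes,large_wader,VU,FALSE
Porphyrio porphyrio,Porphyrio,Rallidae,Gruiformes,none,LC,FALSE
Amaurornis phoenicurus,Amaurornis,Rallidae,Gruiformes,none,LC,FALSE
Gallinula chloropus,Gallinula,Rallidae,Gruiformes,none,LC,FALSE
Podiceps cristatus,Podiceps,Podicipedidae,Podicipediformes,diving,VU,FALSE
Tachybaptus ruficollis,Tachybaptus,Podicipedidae,Podicipediformes,diving,LC,TRUE
Phalacrocorax carbo,Phalacrocorax,Phalacrocoracidae,Suliformes,diving,LC,FALSE
Phalacrocorax niger,Phalacrocorax,Phalacrocoracidae,Suliformes,large_wader,LC,FALSE
Anhinga melanogaster,Anhinga,Anhingidae,Anhingiformes,diving,LC,TRUE
Anastomus oscitans,Anastomus,Ciconiidae,Ciconiiformes,large_wader,LC,FALSE
Alcedo atthis,Alcedo,Alcedinidae,Coraciiformes,none,LC,FALSE
Motacilla alba,Motacilla,Motacillidae,Passeriformes,none,LC,FALSE
Haliastur indus,Haliastur,Accipitridae,Accipitriformes,none,LC,FALSE
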
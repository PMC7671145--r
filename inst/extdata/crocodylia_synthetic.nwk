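((((Alligator_mississippiensis:0.1186988452,Alligator_sinensis:0.1186988452):0.1945492852,((Caiman_crocodilus:0.1186988452,Caiman_latirostris:0.1186988452):0.0741279977,Melanosuchus_niger:0.1928268429):0.1204212875):0.1028084248,(Paleosuchus_palpebrosus:0.1186988452,Paleosuchus_trigonatus:0.1186988452):0.29735771):0.5839434448,(((Osteolaemus_tetraspis:0.1186988452,Mecistops_cataphractus:0.1186988452):0.5571870228,(((Crocodylus_niloticus_suchus:0.3132481304,(Crocodylus_acutus:0.2561128518,(Crocodylus_intermedius:0.1928268429,(Crocodylus_moreletii:0.1186988452,Crocodylus_rhombifer:0.1186988452):0.0741279977):0.06328600892):0.05713527861):0.1502149264,(Crocodylus_palustris:0.1928268429,(Crocodylus_siamensis:0.1186988452,Crocodylus_porosus:0.1186988452):0.0741279977):0.2706362139):0.1314404017,(Crocodylus_johnstoni:0.1928268429,(Crocodylus_mindorensis:0.1186988452,Crocodylus_novaeguineae:0.1186988452):0.0741279977):0.4020766156):0.08098240952):0.077012089,(Gavialis_gangeticus:0.1186988452,Tomistoma_schlegelii:0.1186988452):0.6341991118):0.247102043);
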
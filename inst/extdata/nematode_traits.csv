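# Reference nematode trait table: trophic group (Ba/Fu/Pp/Op), c-p value
# (1-5, colonizer-persister scale) and mean fresh body weight (ug per
# individual, literature-scale representative values). Edit or replace via
# load_traits() for study-specific assignments.
genus,trophic_group,cp_value,fresh_weight_ug,predator
Rhabditis,Ba,1,2.8,FALSE
Caenorhabditis,Ba,1,0.6,FALSE
Protorhabditis,Ba,1,0.25,FALSE
Mesorhabditis,Ba,1,1.1,FALSE
Panagrolaimus,Ba,1,0.65,FALSE
Eucephalobus,Ba,2,0.55,FALSE
Acrobeloides,Ba,2,0.3,FALSE
Acrobeles,Ba,2,0.7,FALSE
Chiloplacus,Ba,2,0.6,FALSE
Cephalobus,Ba,2,0.45,FALSE
Cervidellus,Ba,2,0.2,FALSE
Plectus,Ba,2,1.2,FALSE
Anaplectus,Ba,2,1.6,FALSE
Wilsonema,Ba,2,0.15,FALSE
Monhystera,Ba,2,0.35,FALSE
Eumonhystera,Ba,2,0.2,FALSE
Prochromadora,Ba,3,0.3,FALSE
Prismatolaimus,Ba,3,0.5,FALSE
Alaimus,Ba,4,0.3,FALSE
Aphelenchoides,Fu,2,0.15,FALSE
Aphelenchus,Fu,2,0.3,FALSE
Ditylenchus,Fu,2,0.25,FALSE
Filenchus,Fu,2,0.2,FALSE
Paraphelenchus,Fu,2,0.35,FALSE
Tylencholaimus,Fu,4,0.6,FALSE
Tylenchus,Pp,2,0.25,FALSE
Psilenchus,Pp,2,0.4,FALSE
Malenchus,Pp,2,0.15,FALSE
Paratylenchus,Pp,2,0.1,FALSE
Pratylenchus,Pp,3,0.35,FALSE
Helicotylenchus,Pp,3,0.8,FALSE
Rotylenchus,Pp,3,1.2,FALSE
Criconemoides,Pp,3,0.7,FALSE
Longidorus,Pp,5,12,FALSE
Tripyla,Op,3,1.5,TRUE
Clarkus,Op,4,3.2,TRUE
Mylonchulus,Op,4,2.5,TRUE
Anatonchus,Op,4,6,TRUE
Eudorylaimus,Op,4,4.4,FALSE
Mesodorylaimus,Op,4,1.8,FALSE
Microdorylaimus,Op,4,0.5,FALSE
Thonus,Op,4,1.6,FALSE
Aporcelaimus,Op,5,18,TRUE
Aporcelaimellus,Op,5,10,FALSE
Discolaimus,Op,5,5.5,TRUE
Oxydirus,Op,5,3,FALSE
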
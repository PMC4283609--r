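genus,origin_continent,recording_continent,region,age_max,age_min,locality
Thinobadistes,SA,NA,temperate,10.9,10.1,McGehee Farm
Pliometanastes,SA,NA,temperate,10.7,10.0,McGehee Farm
Megalonyx,SA,NA,temperate,9.2,8.6,
Cyonasua,NA,SA,temperate,7.5,7.1,
Neochoerus,SA,NA,temperate,6.8,6.1,
Chapalmalania,NA,SA,temperate,5.9,5.3,
Erethizon,SA,NA,temperate,5.8,5.2,
Tapirus,NA,SA,temperate,4.8,4.3,
Platygonus,NA,SA,temperate,4.7,4.1,
Hydrochoerus,SA,NA,temperate,4.5,4.0,
Glyptotherium,SA,NA,temperate,4.4,3.9,
Conepatus,NA,SA,temperate,4.2,3.7,
Paramylodon,SA,NA,temperate,4.1,3.6,
Galictis,NA,SA,temperate,4.0,3.5,
Hemiauchenia,NA,SA,temperate,3.9,3.4,
Dasypus,SA,NA,temperate,3.9,3.4,
Theriodictis,NA,SA,temperate,3.8,3.3,
Stegomastodon,NA,SA,temperate,3.8,3.1,
Holmesina,SA,NA,temperate,3.7,3.2,
Lama,NA,SA,temperate,3.6,3.2,
Dusicyon,NA,SA,temperate,3.5,3.05,
Arctotherium,NA,SA,temperate,2.9,2.4,
Hippidion,NA,SA,temperate,2.8,2.3,
Sylvilagus,NA,SA,temperate,2.7,2.2,
Akodon,NA,SA,temperate,2.6,2.1,
Equus,NA,SA,temperate,1.9,1.4,
Protocyon,NA,SA,temperate,1.9,1.5,
Odocoileus,NA,SA,temperate,1.9,1.3,
Nothrotheriops,SA,NA,temperate,1.9,1.45,
Tayassu,NA,SA,temperate,1.9,1.35,
Smilodon,NA,SA,temperate,1.8,1.3,
Lycalopex,NA,SA,temperate,1.8,1.4,
Palaeolama,NA,SA,temperate,1.8,1.2,
Pampatherium,SA,NA,temperate,1.8,1.35,
Puma,NA,SA,temperate,1.7,1.2,
Cerdocyon,NA,SA,temperate,1.7,1.3,
Lontra,NA,SA,temperate,1.7,1.25,
Didelphis,SA,NA,temperate,1.7,1.2,
Panthera,NA,SA,temperate,1.6,1.1,
Morenelaphus,NA,SA,temperate,1.6,1.2,
Leopardus,NA,SA,temperate,1.6,1.15,
Tremarctos,NA,SA,temperate,1.6,1.1,
Antifer,NA,SA,temperate,1.5,1.1,
Vicugna,NA,SA,temperate,1.5,1.05,
Calomys,NA,SA,temperate,1.5,1.0,
Amahuacatherium,NA,SA,tropical,9.6,8.9,Acre
Surameryx,NA,SA,tropical,9.5,8.8,Acre
Sylvochoerus,NA,SA,tropical,9.5,8.7,Acre
Waldochoerus,NA,SA,tropical,9.4,8.6,Acre
Zacatzontli,SA,NA,tropical,6.8,6.0,
Cuvieronius,NA,SA,tropical,6.5,5.8,
Notiomastodon,NA,SA,tropical,4.6,4.0,
Eremotherium,SA,NA,tropical,4.4,3.8,
Canis,NA,SA,tropical,3.9,3.3,
Mixotoxodon,SA,NA,tropical,1.9,1.4,
Coendou,SA,NA,tropical,1.9,1.45,
Pecari,NA,SA,tropical,1.9,1.35,
Pachyarmatherium,SA,NA,tropical,1.8,1.3,
Mazama,NA,SA,tropical,1.8,1.25,
Eira,NA,SA,tropical,1.9,1.3,
Choloepus,SA,NA,tropical,1.7,1.2,
Nasua,NA,SA,tropical,1.7,1.15,
Chrysocyon,NA,SA,tropical,1.7,1.1,
Procyon,NA,SA,tropical,1.6,1.1,
Herpailurus,NA,SA,tropical,1.6,1.05,
Bassaricyon,NA,SA,tropical,1.5,1.05,
Speothos,NA,SA,tropical,1.8,1.2,
Nothrotherium,SA,NA,tropical,1.5,1.0,
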
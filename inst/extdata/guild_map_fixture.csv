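genus,guild,exclude_flag,substrate_complexity
Pseudomonas,Aerobic heterotroph,FALSE,complex
Bacillus,Aerobic heterotroph,FALSE,complex
Flavobacterium,Aerobic heterotroph,FALSE,complex
Arthrobacter,Aerobic heterotroph,FALSE,complex
Acinetobacter,Aerobic heterotroph,FALSE,complex
Rhodococcus,Aerobic heterotroph,FALSE,complex
Sphingomonas,Aerobic heterotroph,FALSE,complex
Micrococcus,Aerobic heterotroph,FALSE,complex
Streptomyces,Aerobic heterotroph,FALSE,complex
Escherichia,Aerobic heterotroph,FALSE,complex
Enterobacter,Aerobic heterotroph,FALSE,complex
Klebsiella,Aerobic heterotroph,FALSE,complex
Clostridium,Fermenting heterotroph,FALSE,complex
Bacteroides,Fermenting heterotroph,FALSE,complex
Prevotella,Fermenting heterotroph,FALSE,complex
Ruminococcus,Fermenting heterotroph,FALSE,complex
Lactobacillus,Fermenting heterotroph,FALSE,complex
Bifidobacterium,Fermenting heterotroph,FALSE,complex
Butyrivibrio,Fermenting heterotroph,FALSE,complex
Nitrosomonas,Ammonia oxidizer,FALSE,simple
Nitrosospira,Ammonia oxidizer,FALSE,simple
Nitrosococcus,Ammonia oxidizer,FALSE,simple
Nitrobacter,Nitrite oxidizer,FALSE,simple
Nitrospira,Nitrite oxidizer,FALSE,simple
Nitrococcus,Nitrite oxidizer,FALSE,simple
Brocadia,ANAMOX,FALSE,simple
Kuenenia,ANAMOX,FALSE,simple
Anammoxoglobus,ANAMOX,FALSE,simple
Desulfobacter,Sulphate reducer (complete ox),FALSE,complex
Desulfococcus,Sulphate reducer (complete ox),FALSE,complex
Desulfobacterium,Sulphate reducer (complete ox),FALSE,complex
Desulfovibrio,Sulphate reducer (partial ox to acetate),FALSE,complex
Desulfobulbus,Sulphate reducer (partial ox to acetate),FALSE,complex
Desulfotomaculum,Sulphate reducer (partial ox to acetate),FALSE,complex
Desulfomicrobium,Sulphate reducer (H2),FALSE,complex
Desulfonatronum,Sulphate reducer (H2),FALSE,complex
Thiobacillus,Sulphur oxidizer,FALSE,simple
Acidithiobacillus,Sulphur oxidizer,FALSE,simple
Beggiatoa,Sulphur oxidizer,FALSE,simple
Thiothrix,Sulphur oxidizer,FALSE,simple
Geobacter,Iron III reducer,FALSE,complex
Geothrix,Iron III reducer,FALSE,complex
Ferribacterium,Iron III reducer,FALSE,complex
Hydrogenobacter,Hydrogen oxidizer,FALSE,simple
Hydrogenophaga,Hydrogen oxidizer,FALSE,simple
Aquifex,Hydrogen oxidizer,FALSE,simple
Methylococcus,Methanotroph,FALSE,simple
Methylomonas,Methanotroph,FALSE,simple
Methylosinus,Methanotroph,FALSE,simple
Methylobacterium,Methylotroph (methanol),FALSE,simple
Methylophilus,Methylotroph (methanol),FALSE,simple
Hyphomicrobium,Methylotroph (methanol),FALSE,simple
Methanosaeta,Acetoclastic methanogen,FALSE,simple
Methanothrix,Acetoclastic methanogen,FALSE,simple
Methanobacterium,Hydrogen oxidizing methanogen,FALSE,simple
Methanobrevibacter,Hydrogen oxidizing methanogen,FALSE,simple
Methanospirillum,Hydrogen oxidizing methanogen,FALSE,simple
Methanolobus,Methylotrophic methanogen,FALSE,simple
Methanococcoides,Methylotrophic methanogen,FALSE,simple
Methanosarcina,,TRUE,
Shewanella,,TRUE,
Rhodopseudomonas,,TRUE,
Chlorobium,,TRUE,
Synechococcus,,TRUE,
Prochlorococcus,,TRUE,
Chloroflexus,,TRUE,
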
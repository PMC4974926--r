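bee_species,total_nests
Anthidium andinum,6
Anthidium decaspilum,54
Anthidium rubripes,31
Anthidium vigintipunctatum,39
Megachile leucographa,222
Megachile sp. C,17
Megachile ctenophora,74
Mourecotelles triciliatus,3
Trichothurgus laticeps,59
Xylocopa atamisquensis,88
Xylocopa splendidula,5
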
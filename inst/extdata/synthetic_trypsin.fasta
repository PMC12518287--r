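>SYN_TRYP synthetic trypsin-like protease (synthetic stand-in sequence for autolysis filtering examples; not a database entry)
MKTFIALLLAAVAFSAEDKIVGGYTCAANSVPYQVSLNSGYHFCGGSLINDQWVVSAAHC
YKSRIQVRLGEHNIDVLEGNEQFINAAKIITHPNFNGNTLDNDIMLIKLSSPATLNSRVA
TVSLPRSCAAAGTECLISGWGNTKSSGSSYPSLLQCLKAPVLSDSSCKSSYPGQITGNMI
CVGFLEGGKDSCQGDSGGPVVCNGQLQGIVSWGYGCAQKNKPGVYTKVCNYVNWIQQTIA
AN
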
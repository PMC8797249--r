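>18S synthetic stand-in sequence
UCCACGGAUCAAGAUCGAUGACAAGCUCAACUCAGGGCCCUCGUGUUACCCUCCCUCUGCAGUCCUCUAC
UCUCUAAAGCAGCAAAUGGCGCUGCGGCACUCUAGGAGGGCGAACCUGUACUCAAAAGGAAAAGUGCUGA
UAUUGUACAAUGGGCACAUAGUGCGCAGCAAAUCUGUAAGAAUGGUCAAGCAUCGACCCCUUCGAGUCUC
UCACCUACCUGCCAUGUAACCCUCAUAAUGGCUGAAACGGCUAGCUAGAUUACCGCCUCAUAUCACGUCC
UAUUGGGAUCGGUCAUCUUUGUCACCUCCCGCGCCAAAUCGACUCUAUUAGUCAACUCCGUUUCAACUGA
CAUGUCGGGUGGACUCGGGUAUUUGGUGACUCCCUCUACAGUUAGGGUGCAGGUGCAAGGAUAUAGAACC
UCCUCAGUUGAGACCGCAUCUGCUGACUUCGGGCGAUUCGUACGUCUCGCUUAUUGACCAACGCUCUUUG
CCUAAUGGAGUACUCAUUCGCGUCGUUAGUUAGCAAGUAUCUGUCCGAUUGUAGUAGAGAGUAGAUGACC
GGGAUCACAUUUCCUACCAGCAGGGCACGGGAGAUAUCAUUGAAUGAGCAAUAUACGUCUCCGAUGUUUG
UCGGCGCGGCCAAUUACAACCGCGGAGUGGUAAGCUUUUAUUAUGAAGUAACCUAAACUAUGGGAGGACC
AGUCCUUCACCUGGCAAGGAGGCAGCGCGGGAGCAGCGAAAUACGCGGGAAACGUCCGUCUGCAUCCUAG
CGACAUUAGAACUGGAUUCUUUGCUAGGCUUGAAUGAAGUCGAUAGAUCACCAAUUUCGAUAGACAUACC
CCCGGUGGGUUCGGAACAAUUUGACUGCACUUUUUCUCGUAAGUUGAAACGGCUCUUAGCGCAUGCGGGA
UGAUUCGCGGCCUACAAAAAAGGUGUGCGCGACCAAAACCAAUGGAGCGAAACCACUUGAUACCAAGCCA
UGCAGGUGGGCAACCUUGACCUCUCAACCACAACAGUUUAAUGUGGCGGGGGCCGACUGGCGGUUUAUUA
ACGCCAUGUAUGGAGUUGCGGAACCACCCCGCGUAGAGCGUACCUCCGGUUGGUUCUCGUUCUUAUUUAG
AAAUGUGCUUCUGGAUGCCCUUCGAGAAAUACGUAACCUAAUCAUACAUCAAAUGAUCGAUAACGCCAGA
CCUGUAGUGCACUAUCUGACUACAUGAGGUUGCAGGUAGAUUAUUGGCACUAAUAAUACCCCGCUAUUCU
CCGCUUAAGGACAGCUACCGGCAUAAUCCUUUAGGCGUUCCUCAAGUAGCGCAUUUCACGAUGCCCAGGU
UUCGCACGAGCGUACUACUAUAAGAAUGAAUCCACGACUAGUUGUCCUCCUCAGUUAGUGAGGAACCUAG
AGAGACCUUGUAGGCACUGGAAUGCCCCUUUUGGCUCUCCGCCGAGGAGGGAACUUGGUUCUCUUCAGAU
GCUCACCUACAGGUCGUGGUCAGCACGUUCGCUUGAUGCGCGUAUGCUCCGACGACGGGCUAAGCUGUCU
CUCAAUGUGCCGGGGGAUAUAUUGACUCACGGAAGUCCACCCGGCAUUGCACUAAUAGGAACGCUCGCCA
GAUUGUUGAUAACUGUCCGUGAGGCCGGUCUACAACCGCGGACUCGACUGAUCAGAGUGACCUUCAUUAA
UUAGCAGAACGCAUUUGUCAUAUGCCUGGCUACAUAUGCGCGGUCGCUACCUGGGUGUCGCGAGGAUACU
CGCACCAGACUGCUUUCUGGACAUGGCCAAAAGAGCUAGCCAAGAAGGAAGGUUUCUCGUUCACAGUGAG
CAUGCU
>5.8S synthetic stand-in sequence
UAUUGGCACAGUCUGGUGGCGUCUUCUCAGUUGCGGCCGCGCACGCUGAUUUGUCCAGCAAGGUCUACGC
GCUAGAGAACUGACGUGUACAAGGAGGCAACAAAAACGGAGGCGUAUAUGCCAAUCCCGUAGGCCGGGAC
AGGGACAGCUCGUUUGCGGACU
>28S synthetic stand-in sequence
AUUUGCAUGAUCCCUGAGGUUGAAAUAAGGUAAUUUCGACCAGUUGUGUCGCGCUAUAGCUUCGCGGCGG
UCUUGCUCUUAUGUGGCGUGUGCCUUUUCGUUUGUUUCAGCUUUUUCGCCCAAUGGUCGGCGCACCUUAG
UCGAUACCGGCAUAUGGUGUGAAAUUUUAUGAGAGCCUUUUUACCUCCUAAUCGGCACUUCAGUGAUACA
ACGUAAGAUCAUAUGUGUAGAGACUAAGGGAGCCAUUUAUGUUCGCUAGGCAAUGCGAGAGUGCGUGUUG
CGCCUAGCUCGGAACGCUUCUUAUCCUCAUUCCCCCGUGAUUGGGUAUUACUCGCUCAUCCCUAACGAAG
GUUCAAGACAACUGGUCGGGAUGGACUGAAGGGGUUUUGGCGAAAAACACUGCAAUUUUCCCUAUGACAG
UGGUUUCACUUGAGCACUCUUAAAGUACGCCAUAUCUACUGGGCUACUCAUUCGGUCGAGUUGUUACGUA
AUGGUAGAGAACAGGCUGAACAUUCAUACUGCUUUACCUCCUCUUUUCGCACGAUACUCAGGUUUCAGCU
AGUAUGAGUUUCGACUGUCCUACCCGGUGUAAAGCUACCAUAGUCAUCCAUUCUCCGUGUCGGGGCACAC
CAGCUCAGCCGAUGUACGUGCCUAUAGAUGGAGGCAAGUAGUAUGCAUACACCCCUCCGACUCCACUGAA
GGUCGUCGAGCUGGGCCUUCUACUCUUGCUCGUGCUAAUUCCCUUUAUCAACAUCCGAACACGACACCGC
GGUUAGUUGCGAUCUUGUAACAUAGGACUAGGAAGUUCGGCAAGGGCCCACUCGUUCGCAUAUCCAUGAG
UAUUACCGACCGCCCAGGGAUAAAAAUCGCGACUUCGUCAUUUAAUCUGUACUAGCAAAUUGCGUAGAAU
UCCCCUUGAUCGGCCCAAGCAGGGAAUUUGAUAUCAUCCGAACGAGUGAAUUAAUGGCAGCGCUCACGGG
CAUUGGAUCUCGGAGGAUCAGGAGGUUCCAUAUCGUAGAGCCUAACCUCUAGGACACACUUCGAUAAGUG
CGCGGAGGCUGGGUGGUCGGUUCGAACUUAUCUGUUAGGCACCCUCUGGAUCUAACGCGUUCCGCGGGAU
UCCAGGAAUUCAAAUGGCAUUAGUGCUAGGGUGGAUCACUCGGUCGAAACAGCACCAACGCAGACUGAGC
CCGUACUUCCGCGGGAGCCGUUUAUACUCUAAUCGACAUUGGGUAGUUGUCAACUAGAGUCGCAAGCCCA
UCCACCUCUCGCGUCGGUGUAACAGGCCGAUGUGACAUUACAGUAUGCCAUUUUUCGAGGCGUUGUUGAC
UUCGGAACUCCCUGACAUUUCGGGAUCUUAUUACCAGGCGAGGCGGCACGCGAAUGCCCAAUAUGACUGA
ACGCGACGAUACCGGACGUUCACACGAUAAUACGUAAAUAACACAAUCACUGCAAUUUCACAGGAAGAGC
UACCCCUAAUGCAGAAUCCGUAAACGUAACAAAGAGAAUGUGGCGUAACUGAGCCAUUGCUUGGCUCAAC
AGGCGGAGACCCCCUUUGAUCUAAUUUCGAGGCGCGCACAGGGGGAACGUUAUAGUCACUUAGCACCGGG
CGUUGGGGAUCGAGACGUAAGCCGAGCGUUAUAGUCUGUAGGCUUCCUUGCAACACACGACUUGUCUUAU
UAUGAAUCUUACUUGUGAUUGAGUGCGGCCUCCGUGGAUUUUGAAGCGGUCUAGAGGUACCAUGUCCAGU
GGCCGUCGAUUGCCCGAUUCUAACUCCUUUUGAACGAUUUCUACGCGCUCCUGCCCGGCACCGUAGGCUG
AGUUACAUUGCCGAACAACCUAUCGCAACCUAUACCUAGAAUUUACGGGUAAUACUCGCGUAUCAAAUUA
AAGUAGAUGUACCCGUCCUGUAAUGUAUGGCAGCUCGUAUUUAGCUUUUCUUCUCGGGAUAAUAAGGCAC
CGGUAAAACGGCGGCUCUGACGUGCCGAAGACUGUUUCGAUCUUUGGCAUCUGCGCGAGAAAUUUUCUUC
AUACGGGCCAAUGACCGUAGUGGGCCGGGCGCAUGGCUCCAACGGCUGGCCAACCCCUUACGGCCGACCA
ACUAGUACACAGACGCGAAAUUGACGCGAGCUCUCACAUAAAGGAUUACAUGCUCGGCAGCUGCUCUACU
CCUCGAUUAAGCCCUUCCAAUUCAUGUGAGCGACUGUGGAUGCGACAGCUGGUCUGGAGAUGGCCUGCGA
UAACCGUGCCCAACGCGAUAGCCGCGAGUUUUUCUGCGUGUCUGCAUCGCGGGGGGCAGAUAAACACGAG
UUUUCUGUCGUAGGACUGGAAGUACGACCCAGAUACAAGCGAGGGCGCUGCUCUGGGAAUAUUCACUGAG
AGCUUACCACGGUAGGAGGCGACUGGGACUCUAUCUCCCUUCAUGGUUGCUGCCAAGAGGUGGUUGCGUC
GAGCCUCCCACUUCCGAUCAUGACUCGCUAAGUGUGGGUCCUGAACACAAUUACUAGAACACUCGCUGAG
UAUCUUCGGGUCACUAAUUUAACGCUGACCGUCCCUGUAUAGGUAUCCGGCCGGCUCUUGUUCCCUGUAC
GUAUACUCGAGAUGUGUUAUCCUAAUCCCCGCGAAUUCAUUUAUUCUCUGUGGUGCGGUUGUAAAGGUUG
UACCAUAUGGUACAGCCAAGACUGGUAAAGUGCUAGGUGCCUUACCAUGAGUGCGCGCGAUAUGCAAUAA
AGACACGUGAGUGUGCCCCGAACAGGCGUCCGCCCAUACUGUUAGUGCCCAACCGCCGGUUUGGAGUUAA
CCCACGGUGUAGUGACAGGCCUCAGCAAGAACAGCUCUUAUCGGGGCAUUAACCACGUUGGUUCAGUUAG
GGGGAUUAAAUUAGGAUGUCACGUGAUCGGAUACUGCUUCACCUGCUGUGCCGCUGAGCGUAGUGACGAG
GCGCCUCUCUCUCUGAAUCUUUCUUCGGACAGAAAGGCCAACCGAUUUCCGUUACUCAUAGAGCCCCCCG
UCUGCUAAUCGUUCAGGGACGUAGGCUACUCCGUAGGAAGGCCGUCGCUUGGAGGGACAUACCCAUUGUA
CGAUAAUCCGACGACUGGUGCAGGACGAUGUGUGAGACCGUGUCGGAAAUGUCUGACGCAAUGGCCAGAA
UGGUUUUGUUACCGUGACUAGCGUGAUCGGCACCCCUAAGAGUUUAAUCUAAGAGGAACAAUACUGGUCC
UUCGACACUAUUUAACGUUCCAUAACGCACCAAGAAAGUAGCCCGAAUGCAUCGUAGACACGAGUUUCCU
GGCGCAUUUGUUGUGAGAGUGGCUUUGUAUUUCUUGACCCCUUCUAUCCUUAGAUUAGCGGCACUUGACU
CACAAUUAUUAGAUGGAGAUCGGCGGAGGCACAGCCGUAGAGUCUUGGCGUGUGUUCGCAGCCGUGCAAU
GUCCCUUUCCCAUCGUGGUAAAGAGUAAGGACCACUUCGCGCAUCCCGUUUAUGAGCAGGGAUAUCAUCC
GUGACGGUGUCCCCAGGACGCAAGAGUGGACGUGCGCGCUAAGCACUGCCUUACUCUCUGGAGGCCAUCU
UAAACUUGUUAAAGCGCCUCAGCUAGUUCAUAGACCCAUAGGGUCUGACUUGGUAGCGCACGUGGAUAUG
CUACUGCUUUGGAGGUUUCCCGAUUACACGUCAGCGAAGACCAUGGAGCGAAACGCAGUAUAGAGUGAUU
GGUACCGAAUAAUCCUAGGCUAUUUCAAUCGGGAUGUAAUCAAGCCUGGGAACGUCCAGGUGGCAUUCGA
GACCGGAAAAAGCCUCCCGCGUCCCGUCAAAUUGAUAUGAUCAUGGCCCCGCCCUUUGGCCUAUAUUACC
GGCGACUUCACGUACCUGCAACCUGUAGUUCCUAGUCUAUCUAACAAUACGCCCGUACUAUAGGUGGUGU
GUGUCCUUGGAUGAUAGAUUAGCAUAAGGGCUGCCCGCAGCAGGCAUUGAGGUAGCAUGGGGCACCUCAG
AGCAAACGUUAUCUCAUCGUGGCAUCGACGCACCAUCGGAACCCUCUCCUAGAGGCAUCCGCGUCCUCCG
UCGGCUUGGGUCUCACCCGAUGUCCUGAACUGGGAAAGUGGGUGCCUCUACCCCA
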
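>SYN1 synthetic membrane-like protein 1
RMGRRVFTLQYMSFRASGSNMRKVHLIFTLVWYHKAPDGKAVSVTEMMYRFETLKSTQVA
SKSRNMHACTVLAGALLWRVRTTAFGKIVFFRTDSFSSCAVSAQGQTSLFIRSLQDSRGY
GRTTIQSRSGFYLVSFVKPVTLVVCGIVSCHGASLGQGSMRTRTHKQLDLTTFTSETIIE
LSLTIRGGWSSFGLQRNGDKYITSTEKFYQLYTGVTLKTSSLAMGCSRAFLLLEGINANS
KASGACFLKYRSDLVFRTGFKERMGWTELYGIMDSTNEEPSQSQLYT
>SYN2 synthetic membrane-like protein 2
LGFTAGSYQCRTVWIQHMEATTSFRSKFKSACRVNVPSDVSKITRSSTALPKLYFVCSFT
RTWSGILVQPANPLDATQSSSQTGVDAALGLERSVYVKVGEVKAKTAHSKTICETSNPIY
IIPPITIYEMTAIVRAYCIVRTPVGNGRAATLKVLERNMNLKFYTAYNMAGVDDFATYKV
YLRKVPTGVSILLMLLQTEPSTGVWDEATTAMPQLLSVVVCTPAWTSSRSKETRASSYMH
THITHNAGTTSMSHLSTMTSVLMTATSLETGYHLVAINMVKTVVQRGGFGFTTLMIPSGN
RNSGIEKEGVASTMKTGRRSPFSCIPRYAFARSEYLEHNLDF
>SYN3 synthetic membrane-like protein 3
STKLIDASIESKLLESPKRNAASSTMAFFRIQSVVPKNFYTRYVRIKAEYGRYRKNDGSD
ASRSFSSNGAMKSTFSLVLTHYSDSLTNMSKIYFRPSHSTVSYYRTVLLDSWWGVEITRQ
STSSSIRSSQTAYWFTVGVAVSFVSPGSLYAFIDGASVTFFVCKKGAEKKVRHSQESFLS
SKTAEAAISGTYLIPTVSRGSHGCRTCQGIQTKYVRVLFSSGWLLVSTVSGFYAEGRLQS
GRYPSGSIVILFYEEVETHKASLPTFLGSSNGCPSDGESGETGAVEASQHFAMGSLNVTQ
VGTFTMKDVILSISGLGRAALTAEKISEKSTLKDVWQPSPKSIPFDAIFFHFKRMKFTHR
AVLETRDCVLVVTGRFSSLTYSRARQSNSCPNQPGEWDIRWLPTGLVSGAAGTDTETV
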
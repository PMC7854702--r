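>synthetic_phyA_pea_like SYNTHETIC stand-in: phytochrome-A-like sequence (pea phyA homolog analog); NOT UniProt P15001
MSSSRPTQSSSNSRSGSNSSRARQSSQARVLAQTTLDAELNAEYEESGDSFDYSKSVRVT
TSVAAPQQHVPEQQITAYLHKIQRGGLIQPFGCMLAVDESSFKIIGFSENCFDLLGLTSD
HSLINNGSLDSLFHAPSASALSKALGFAEVSLLNPILVHCKTSGKPFYAIVHRVTGSLII
DFEPVKPYEVPMTAAGALQSYKLAAKAISRLQSLPSGSMERLCDTMVQEVFELTGYDRVM
AYKFHEDDHGEVFAEITKPGLEPYLGLHYPATDIPQAARFLFMKNKVRMICDCSATPVKV
IQDKSLSQPISLSGSTLRAPHSCHLQYMENMNSIASLVMAVVVNENEDDESSDATIQPQK
KKRLWGLVVCHNTTPRFVPFPLRYACEFLAQVFAVHVNKELELENQILEKNILRTQTLLC
DMLMRDAPLGIVTQSPNIMDLVKCDGAALLYGNKVWRLQTAPTESQIHDIAFWLSEVHRD
STGLSTDSLHDAGFPRALSLGDSVCGMAAVRISSKDMIFWFRSHTAAEIRWGGAKHDPSD
KDDSRRMHPRLSFKAFLEVVKMKSLPWSDYEMDAIHSLQLILRGTLNDAIKGNSSLAIEN
KIGDLKLDGLAELQAVTSEMVRLMETATVPILAVDSNGLVNGWNTKIAELTGLRVDEAIG
RHILTVVEESSVPIVQRMLYLALQGKEEQEVKFEIKTHGSKTDSGPVILVVNACASRDLH
DHVVGVCFVAQDITAQKTVMDKFTRIEGDYKAIVQNPNPLIPPIFGTDEFGWCSEWNPAM
SKLTGLKREEVMDKMLLGEVFGTQKSCCRLKNQEAFVNLGVVLNNAVTGQESEKVPFGFF
ARNGKYVECLLCVNKRLNREGVVTGVFCFLQLASHELQQALAVQRRQEKKCYARMKELAY
IRQEIKNPLNGIRFTHKLLESTELNDEQRRLLRTSALCQEQLSKILDDSDLESIEECYME
MNTMEFNLGEVLSVVISQVMILSREKQIQIIRDIPDEIKTLSVYGDQIRIQQVLSDFLLN
AIRFSPSPGRVTIACSLSKNSIGENVHLIHLEFRIVHPAPGIPEELIQEMFHNSRWVTQE
GLGLNLSRNLLNKMNGEVQYIREGERCYFLIDLELPQKRTLIS
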
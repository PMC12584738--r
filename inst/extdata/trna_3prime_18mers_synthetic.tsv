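label	trna18
Pro	TGGCGCAGGGTTCGAATC
Phe	TGGTGCGAATTCTGTGGA
Lys	TGGCGCCCGAACAGGGAC
decoy1	ACCTAGGACCTTTAGGCA
decoy2	GATTACACATGGTCCTAA
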
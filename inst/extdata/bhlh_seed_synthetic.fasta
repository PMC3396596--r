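>Seed|bhlh01 synthetic bHLH seed
RRKPANARERRRWQWINDAFEGLRSHIPTLPY-KRL-KIDTLRLAIGYINFLSI
>Seed|bhlh02 synthetic bHLH seed
RRKAA-ARERRRMQSINDAFEGL--KIPTLPYEKRLSKIDTLRLAIGYINFLSE
>Seed|bhlh03 synthetic bHLH seed
RRKAANARHRRRMQSINDNAEGLR-HIPTLPY-KRF-KIDCLRQAIGYINFLCE
>Seed|bhlh04 synthetic bHLH seed
RRKAANARERRRMQSINDAFEGLR-HIPTLPY-KVLFKIDTLRLAIGYINFLSI
>Seed|bhlh05 synthetic bHLH seed
RRKSANARERRRMQSINDAFEGLRSHIPTLPY-KRLSKIDTLRLAIGYCNFLSE
>Seed|bhlh06 synthetic bHLH seed
RRKAANAREIRRMQSINDMFEGLRSHIPTIPYDKRLSKIDTLRLAIGYINFLKE
>Seed|bhlh07 synthetic bHLH seed
RRKAA-AGERRRMNSINDFFEGL--SIPTLPY-KRLSKIDALRLAIGLINFLSE
>Seed|bhlh08 synthetic bHLH seed
RRKAWNARQRRRMQSINDAFEGLR-HIPTLTYEQPLSKIDTLRSAIGYINFLSW
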
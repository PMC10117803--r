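>MycE
TRFVERREKCGNLKDTLLFWQECHQNVSTRKQWVMQPEIQKWHVCYVHWGGVEDNPPMAD
ENLKWNPKPAKGKFCMYWAETGAMSHGLEVVLGVWFTQENTCRKGKGCVVDCPEHWSLMW
WCIKMCKFTEKPNSQTVTKECLWMETRLVGFAPFFMVQSMGPGMEESYLYTYPWCGNAMC
DKVDVSYLNMIADNHPNWQNAPLYWVNLIHFSIEAEILLMWWWCRNKMEFVIYGVENTYT
GSYEINSTMYIMVVQMWYSNWKTVMEQPRWSPKADMV--------HVTPTMSIHLANHEP
VHNIECESPDNDWTWDYNRLEFLEPAFIIHYIGRCCPIYNRFKPVAFRKEYPEEGPAFKH
LGCEFISRFWMRLFHNAAGDATSHEYDPTGSNSVSMVTHHKKHDTTK
>R132
------------------------------------------------------------
------------------------------------------------------------
----------------------------VGIWVWQVNYDSSELYDFVYFLSWYIIQKQNR
ANIGWLRRHDGIKHWCTTITRPETLCHYLEHWNIKLAYSAQACPWVWFGYEARKWTCGHC
AHNGLIHVMEIHVMVLTHFPEVQLMTQVMFKKYIDAREGCEGFQRHWQYELNDSWWLMYD
DIM--------DRFSWAPAPKIYPQIGACPEMNAMAIYCWCKASWLRQLSFDINMSMDCW
KFTTITQEERTHCQEKH------------------------------
>R132_mamavirus
------------------------------------------------------------
------------------------------------------------------------
----------------------------VGIWVFQVNYDSSELYDFVLFLSWDIIQKQNT
ANIGWLRRHKGDKHWCTTITDPENLCHYLEHWNIKLAYSAQACPWVWFGYEARKWTIGAC
AHYGLIFVMEIHVMVLTHFPEVQLMTIVMFKSYADAREGCEGFQRHWQYELNDSWWLMYD
DIS--------DRFFWGPAPKIYPCIGACPTMNAMAIYCWCKASWTRQLSFDINMSMDCI
NFTTITQEERDHGQEKH------------------------------
>R132_hirudovirus
------------------------------------------------------------
------------------------------------------------------------
----------------------------VGIWVWQVNYDSSELYDFVYFLSWYIIAKQIR
ANIGWLRRHDGIKHWCTTITRPETLCHYLEHWMIKLAYSAQQREKVWFGYEARKWTCGHC
AHNGCIDVMEIHVMVLTHFPEVQLMTQVMFKKYIDAREGCEGFQRHWQYELNDSWWEMYD
DIP--------DRFSWAPAPKDYPQIGACWEMTAMAIYCWCKASWLRQLSFDINMSMCCW
KFPTHTDEERTQCQEKH------------------------------
>R132_bombay
------------------------------------------------------------
------------------------------------------------------------
----------------------------VGIWVWQVNYDSMELYDFVFFLSWYIIQKQNR
ANIGWLRRHDGIKHWCTTITDPETLCHYPEHWNGKLAYSAQACPWVWFQYQAAKWTCGHC
AHNGLIHVMEIRVMVLTHFPEFQLMTLVMFKKYIDARVGCEGNQRHWQYELNDRWWLMYD
DIM--------DRFSLAPLPKIYSQNGACPEMNAMAIYCWPKASWLRQLSFDINMSMDCW
KFTSITQEERTHCQEKH------------------------------
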
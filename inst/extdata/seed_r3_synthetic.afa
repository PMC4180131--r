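>seed_r3_01
DVKNYVWSPEEDEILVAHQKYGGNKWSEIAKLLPGRTDNEIKNHWNSTLKR
>seed_r3_02
DVKNYVFSPEEDEILIAHQKYGGNKWSEIAKLLPGRTDNEIKNHWNSTLKR
>seed_r3_03
DIKNYVWSPEEDEILVAHQRYGGNKWSEIAKLLPGRTDNEIKNHWNSTLKR
>seed_r3_04
DVKNFVWSPEEDEILVAHQKYGGNKWSEIAKLAPGRTDNEIKNHWNSTLKR
>seed_r3_05
DVKNYVWSAEEDEILVAHQKYGGNKWSEIAKLLPGRTDNEIKNHWNSSLKR
>seed_r3_06
DVKNYVWSPEEDDILVAHQKYGGSKWSEIAKLLPGRTDNEIKNHWNSTLKR
>seed_r3_07
DVKNYVWSPEEDEILVANQKYGGNKWSEIAKLLPGRTDNEIKNHWNSTLRR
>seed_r3_08
DVRNYVWSPEEDEILVAHQKYGGNKWTEIAKLLPGRTDNDIKNHWNSTLKR
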
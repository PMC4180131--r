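>seed_r2_01
LNKGAVWSKEDNELISYIKAHGEGKWRSLPKRAGGLQRCGKSCRWRLINYLRP
>seed_r2_02
LSKGAVWSKEDNELISFIKAHGEGKWRSLPKRAGGLQRCGKSCRWRLINYLRP
>seed_r2_03
LNKGSVWSKEDNELISYIKAHGEGKWRSMPKRAGGLQRCGKSCRWRLINYLRP
>seed_r2_04
LNKGAVWSKEDNELITYIKAHGEGKWRSLPKRAGGLQRCGKSCRWRLINFLRP
>seed_r2_05
LNKGAVWSKEDNELISYIRAHGEGKWRSLPKRSGGLQRCGKSCRWRLINYLRP
>seed_r2_06
LNKGAVWSKEDDELISYIKAHGEGKWRSLPKRAGGIQRCGKSCRWRLINYLRP
>seed_r2_07
LNKGAVWSKEDNELISYIKAHGDGKWRSLPKRAGGLQRCGKSCRWRLVNYLRP
>seed_r2_08
LNKGAVWSREDNELISYIKAHGEGKWRTLPKRAGGLERCGKSCRWRLINYLRP
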
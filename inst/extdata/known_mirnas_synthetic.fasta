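>nve-miR-100 synthetic stand-in (not a miRBase sequence)
cacccuuagaucugaacuugug
>nve-miR-2023 synthetic stand-in (not a miRBase sequence)
uaaagaaguacauguggcagg
>nve-miR-2022 synthetic stand-in (not a miRBase sequence)
uuuugcuaguggcuuuucucccgu
>hma-miR-2022 synthetic stand-in (not a miRBase sequence)
guuugcuaguggcuuuuguccggu
>nve-miR-2036 synthetic stand-in (not a miRBase sequence)
auauauugcacgacucucuucgug
>nve-miR-2030 synthetic stand-in (not a miRBase sequence)
guagcacaacauucuaagagau
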
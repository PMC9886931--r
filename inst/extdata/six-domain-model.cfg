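# Default six-domain confirmatory model: factor -> indicator list.
metabolism: BUN Cr K P UA
circulation: SBP DBP
liver: AST ALT
salt: Na Cl
inflammation: WBC Plat Hb
protein: TP Alb
cross: Alb metabolism
cross: Hb metabolism
kind: correlated-factors
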
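# Boolean model of the cholesterol regulatory pathway: synthesis from the
# precursor acetyl-CoA to cholesterol, with the cholesterol -> SREBP-SCAP
# feedback and statins inhibition of HMG-CoA reductase.
#
# Conventions: every multi-input node is an AND of its inputs, except
# cholesterol, which is an OR over the two terminal synthesis branches
# (desmosterol / 7-dehydrocholesterol). A NOT marks an inhibitory input.
# Nodes whose rule references themselves are persistent: metabolic inputs
# (acetyl-CoA, NADPH, ATP) hold their state, and the activated SREBP-SCAP
# pool, once released by cholesterol depletion, stays active at the
# sampling timescale (hysteresis). Reconstructed topology; intermediate
# metabolites abridged to the major pathway steps.
Acetyl_CoA = Acetyl_CoA
NADPH = NADPH
ATP = ATP
SREBP_SCAP = SREBP_SCAP OR NOT Cholesterol
HMG_CoA_reductase = SREBP_SCAP AND NOT Statins
Statins = Statins
HMG_CoA = Acetyl_CoA
Mevalonic_acid = HMG_CoA AND HMG_CoA_reductase AND NADPH
Mevalonate_PP = Mevalonic_acid AND ATP
Isopentenyl_PP = Mevalonate_PP
Farnesyl_PP = Isopentenyl_PP
Squalene = Farnesyl_PP
Lanosterol = Squalene
Desmosterol = Lanosterol
Dehydrocholesterol_7 = Lanosterol
Cholesterol = Desmosterol OR Dehydrocholesterol_7
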
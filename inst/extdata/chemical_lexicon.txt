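# Bundled chemical name lexicon: one entry per line, "#" comments.
# Multi-word entries match across token boundaries (longest match first).
potassium carbonate
thiophenol
2-nitrobenzene sulfonamide
N, N-dimethylformamide
N,N-dimethylformamide
dimethylformamide
water
brine
methanol
ethanol
propanol
isopropanol
butanol
ethyl acetate
diethyl ether
petroleum ether
dichloromethane
chloroform
acetone
acetonitrile
tetrahydrofuran
toluene
benzene
styrene
hexane
heptane
pentane
sodium chloride
sodium hydroxide
sodium sulfate
sodium bicarbonate
magnesium sulfate
hydrochloric acid
sulfuric acid
acetic acid
benzoyl peroxide
silica gel
salt
argon
nitrogen
hydrogen
oxygen
helium
potassium
sodium
magnesium
copper
palladium
zinc
iron
DMF
DMSO
THF
EtOAc
MeOH
EtOH
DCM
H2O
MgSO4
Na2SO4
NaCl
NaOH
K2CO3
HCl
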
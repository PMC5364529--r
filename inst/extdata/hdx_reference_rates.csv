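# Poly-DL-alanine-based amide hydrogen-exchange reference parameters for
# exchange into D2O: nearest-neighbour side-chain log10 factors for acid- and
# base-catalysed exchange (Bai/Englander additive log-factor model).
# L = factor applied to the residue's own backbone amide; R = factor applied
# to the amide of the following residue. Side chains are taken in their
# dominant ionization state near neutral pD (Asp/Glu ionized, His neutral).
# Special rows: NT = free N-terminal amine (right factors, applied to the
# amide of residue 2); CT = C-terminal carboxylate (left factors, applied to
# the amide of the final residue). Proline has no exchangeable backbone
# amide; its row carries only right-neighbour factors.
# Reference condition: 293 K, with log10 rate constants
#   log10 kA = 1.62 (M^-1 min^-1), log10 kB = 10.05 (M^-1 min^-1),
#   log10 kW = -1.5 (min^-1), pKD(D2O) = 15.05,
# and Arrhenius activation energies Ea(acid) = 14, Ea(base) = 17,
# Ea(water) = 19 kcal/mol (applied relative to 293 K).
residue,acid_l,acid_r,base_l,base_r
A,0.00,0.00,0.00,0.00
R,-0.59,-0.32,0.08,0.22
N,-0.58,-0.13,0.49,0.32
D,-0.90,-0.12,0.69,0.60
C,-0.54,-0.46,0.62,0.55
E,-0.90,-0.31,-0.11,-0.15
Q,-0.47,-0.27,0.06,0.20
G,-0.22,0.22,0.27,0.17
H,-0.10,-0.10,-0.10,0.14
I,-0.91,-0.59,-0.73,-0.23
L,-0.57,-0.13,-0.58,-0.21
K,-0.56,-0.29,-0.04,0.12
M,-0.64,-0.28,-0.01,0.11
F,-0.52,-0.43,-0.24,0.06
P,0.00,-0.19,0.00,-0.24
S,-0.44,-0.39,0.37,0.30
T,-0.79,-0.47,-0.07,0.20
W,-0.40,-0.44,-0.41,-0.11
Y,-0.41,-0.37,-0.27,0.05
V,-0.74,-0.30,-0.70,-0.14
NT,0.00,-1.32,0.00,1.62
CT,0.96,0.00,-1.80,0.00
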
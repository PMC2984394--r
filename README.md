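# fihcomp

Kinetic modelling of the competition between HIFα and ankyrin-repeat
domain (ARD) proteins for the asparaginyl hydroxylase FIH, and of its
consequences for the hypoxic response.

## The problem

Animal cells sense oxygen through hydroxylation of the transcription
factor subunit HIFα. Prolyl hydroxylases (PHD) hydroxylate the
oxygen-dependent degradation domain (ODD) and so target HIFα for
proteasomal destruction; factor inhibiting HIF (FIH) hydroxylates an
asparagine in the C-terminal transactivation domain (CAD), silencing the
CAD-dependent part of the transcriptional programme. FIH also
hydroxylates ankyrin repeats (ARs), a structural motif present in
hundreds of human proteins. Unhydroxylated ARs bind FIH tightly and
sequester it away from HIFα; FIH, by hydroxylating ARs in an
oxygen-dependent manner, triggers its own release. `fihcomp` implements
dimensionless rate-equation models of this coupled system for systems
biologists who want to explore its input/output behaviour: oxygen
thresholds for FIH release (range finding), sharpened signal/response
curves (ultrasensitivity), and a reoxygenation delay that encodes the
strength and duration of the preceding hypoxic episode (memory).

## The models

All quantities are dimensionless: concentrations relative to the maximal
HIFα level, first-order rates relative to the basal HIFα degradation
rate constant, oxygen relative to the Michaelis constant of PHD for
oxygen (Õ₂; the FIH/ARD reduction uses Ō₂ = Õ₂/α instead, with
α = K_M^FIH/K_M^PHD).

**Full Model** — three ODEs for total HIFα (Ĥ_tot), non-CAD-hydroxylated
HIFα (Ĥ) and unhydroxylated FIH-target repeats (Â):

    dĤ_tot/dτ = 1 − Ĥ_tot (1 + ν′_P)
    dĤ/dτ     = 1 − Ĥ (1 + ν′_P + ν′_FH)
    ε dÂ/dτ   = Â_tot − Â (1 + ε ν′_FA)

The hydroxylation rate functions ν′_P and ν′_FH use tight-binding
(free-substrate) kinetics — the free HIFα pool is the positive root of
the binding quadratic (`free_substrate()`) — and AR competition inflates
the apparent FIH/HIFα dissociation constant,
K̂ᵢ^FH = K̂_D^FH (1 + Â/K̂_D^FA + γÂ_OH/K̂_D^FA). AR hydroxylation
(ν′_FA) is Michaelis–Menten with HIFα as competing inhibitor. Key
parameters: Â_tot (size of the FIH-target repeat pool), γ (FIH affinity
for hydroxylated relative to unhydroxylated repeats) and ε (ARD protein
stability relative to HIFα).

**SKM1** ignores ARD proteins (two ODEs, Michaelis–Menten rates) and is
used for the HRE-occupancy/gene-regime analysis. **SKM2** ignores HIFα
and keeps only FIH/ARD dynamics:

    dÂ/dσ = 1 − Â − βκÂ/(1 + κÂ) · Ō₂/(1 + Ō₂),   F_free = 1/(1 + κÂ)

with sequestration capacity κ = A_tot/K_D^FA and hydroxylation
efficiency β = k_cat^FA F_tot/(k_d^A A_tot).

The package also ships an ankyrin-repeat census toolkit: database
reading (TSV/CSV/FASTA), classification by loop-asparagine and L⁻⁸N
motifs (stringent consensus `21-L(X)₄(AC)(DEN)(ILV)N-29`),
consensus/position-frequency summaries, and a seeded synthetic database
generator whose default composition matches the published census of
1505 human ARs.

## Worked example

```r
library(fihcomp)

p <- full_params()            # A_tot = 100, gamma = 0.02, epsilon = 5
rc <- response_scan("full", p, oxygen_grid(1e-4, 1, 60))

find_threshold(rc$oxygen, rc$F_free)   # 0.0274
hill_coefficient(rc$oxygen, rc$H)      # 1.54
find_peak(rc$oxygen, rc$H_OH)          # value 0.253 at O2 = 0.0212
```

With 100 competing repeats, FIH is released above an oxygen threshold of
about 0.027 (relative to the PHD K_M for oxygen), the decline of
non-CAD-hydroxylated HIFα has an apparent Hill exponent of 1.54 — versus
1.17 without the FIH/AR interaction (`A_tot = 0`), the ultrasensitivity
effect — and CAD-hydroxylated HIFα peaks at intermediate hypoxia
(0.253 at Õ₂ ≈ 0.021), the bell-shaped response that restricts
CADOH-dependent genes to a defined oxygen window.

```r
tr <- equilibrate_then_step("full", p, 0.001, 0.5, duration = 60)
reoxygenation_delay(tr, "F_free")      # 0.339
```

After severe hypoxia (Õ₂ = 0.001) the half-maximal recovery of free FIH
lags reoxygenation by 0.34 HIFα lifetimes; after moderate hypoxia
(Õ₂ = 0.01) the delay is 0.13 — the memory effect. `memory_map()` scans
this delay over severity × duration.

```r
db <- generate_ar_database(synthetic_ar_spec(), seed = 101)
tabulate_ar_classes(classify_ars(db[1:4]))
#>         group repeats   percent proteins
#> 1         L8N     472  31.36213      182
#> 2  L8N_strict     166  11.02990      105
#> 3 Asn_non_L8N     449  29.83389      214
#> 4 Asn_repeats     921  61.19601      252
#> 5     non_Asn     584  38.80399      226
#> 6       total    1505 100.00000      252
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "fihcomp.R", package = "fihcomp")` with subcommands
`steady`, `scan`, `timecourse`, `memory`, `figures`, `classify-ars`,
`consensus` and `gen-ars`.

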
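# albuminbind

Characterization of small-molecule binding to serum albumin from three
spectroscopies, packaged as a tested analysis pipeline with a synthetic-data
generator so every stage can be verified by parameter recovery.

Serum albumin is the main drug-transport protein in plasma; how strongly and
where a candidate molecule binds it shapes the compound's free fraction and
pharmacokinetics. Bench workflows probe this with fluorescence quenching
titrations (binding constant, stoichiometry, quenching mechanism,
thermodynamics, binding-site location via marker competition) and monitor the
protein's structural response with circular dichroism (CD) and FT-IR. This
package implements that entire analysis chain for bovine serum albumin (BSA,
583 residues, the standard HSA surrogate).

## Models

**Fluorescence quenching.** Observed intensities are first corrected for the
inner-filter effect, `F_corr = F_obs · 10^((A_ex + A_em)/2)`. The
Stern–Volmer regression `F0/F = 1 + K_SV [Q]` gives the quenching constant
per temperature and `k_q = K_SV / τ0`; a `K_SV` that falls with temperature
combined with `k_q` above the scatter-collision limit of
2×10¹⁰ dm³ mol⁻¹ s⁻¹ indicates static quenching by a ground-state complex.
The double-logarithm regression

    log10((F0 − F)/F) = log10 Kb + n · log10 [Q]

yields the association constant `Kb` and binding-site number `n`.

**Thermodynamics.** A van't Hoff fit of `ln Kb` on `1/T` gives
`ΔH° = −R·slope` and `ΔS° = R·intercept`; `ΔG° = ΔH° − TΔS° = −RT ln Kb`.
The joint signs classify the dominant forces (both negative: van der
Waals/hydrogen bonding; both positive: hydrophobic; ΔH°<0, ΔS°>0:
electrostatic).

**Site markers.** Binding constants re-measured in the presence of
phenylbutazone (Sudlow site I) and ibuprofen (site II) assign the pocket:
whichever marker depresses `Kb` more occupies the ligand's site.

**CD.** Mean residue ellipticity `MRE = CD_mdeg / (10·C·n·l)`; the α-helix
content at 208 nm is `(−MRE208 − 4000)/(33000 − 4000) × 100 %`, and the
per-ratio table reports the helix loss on ligand addition.

**FT-IR.** The amide-I band (1600–1700 cm⁻¹) is baseline-corrected,
area-normalized, seeded by the minima of a Savitzky–Golay second derivative,
and fitted as a sum of Gaussians; component areas are assigned to secondary
structure classes by center wavenumber (β-sheet 1610–1640, random coil
1640–1650, α-helix 1650–1660, β-turn 1680–1691, β-antiparallel 1691–1700).

A druglikeness module evaluates Lipinski, Veber and TPSA rules over a
user-supplied descriptor table.

## Worked example

Simulate a full titration experiment under the default scenario
(ΔH° = −40 kJ mol⁻¹, ΔS° = −39 J mol⁻¹ K⁻¹, BSA 1×10⁻⁶ mol dm⁻³, molar
ratios 0.1–2.0, temperatures 297/303/308 K) and run the workflow:

```r
library(albuminbind)

sc <- default_scenario()
series <- c(lapply(sc$temperatures, function(T) simulate_titration(sc, T)),
            list(simulate_titration(sc, 297, "PHB"),
                 simulate_titration(sc, 297, "IBP")))
run_fluorescence_workflow(series)
#> <fluorescence_workflow>
#> <mechanism_call> static (K_SV decreasing with T; k_q > 2e10 at 3/3 temperatures)
#> <vant_hoff_fit> dH = -40.00 kJ/mol, dS = -39.00 J/mol/K, r2 = 1.0000
#>   dG(297 K) = -28.42 kJ/mol
#>   dG(303 K) = -28.18 kJ/mol
#>   dG(308 K) = -27.99 kJ/mol
#> <interaction_call> vdW_or_H_bond, spontaneous
#> <site_assignment> site_II_IIIA (Kb ratios: PHB 0.900, IBP 0.500)
```

The workflow recovers the generating thermodynamics exactly (noiseless
input), classifies the quenching as static, the forces as van der
Waals/hydrogen bonding, the binding as spontaneous at all three
temperatures, and — because ibuprofen depresses the apparent `Kb` more than
phenylbutazone — places the ligand in Sudlow site II (subdomain IIIA).

Structural response, from the same scenario defaults:

```r
st <- structure_scenario()
analyze_ftir(simulate_ftir_spectrum(st))$structure
#> <secondary_structure> 3 components
#>   alpha_helix         53.82 %
#>   beta_sheet          29.21 %
#>   beta_turn           16.96 %

helix_loss_table(simulate_cd_series(st))
#> <helix_loss>
#>  ratio MRE208 helix_percent in_range
#>    0.0 -21400          60.0     TRUE
#>    ...
#>   loss (ratio 0 -> 10): 4.30 percentage points
```

The amide-I pipeline recovers the programmed free-BSA composition
(53.8/29.2/17.0) to a tenth of a percentage point, and the CD chain returns
the programmed 4.30-point helix loss.

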
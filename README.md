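# coassembly

Contact-based cluster analysis of peptide–drug–ion co-assembly
trajectories.

Cyclic dihistidine peptides co-assemble with metal ions and small-molecule
drugs into supramolecular clusters that can encapsulate the drug — a
candidate route to self-assembled drug-delivery carriers. Simulations of
such systems produce trajectories of a crowded periodic box (peptides,
drug copies, Zn²⁺, NO₃⁻, Cl⁻), and the scientific questions live at the
cluster level: which components aggregate, how often a drug is
encapsulated, how buried it is, and which ions mediate the contacts. This
package implements that analysis chain for anyone running or emulating
such simulations: structural bioinformaticians and molecular modellers who
need reproducible, tested cluster statistics rather than one-off scripts.

## What it computes

A *contact* joins two components when any inter-atom distance is below a
cutoff d_c (default 3.5 Å) under the minimum-image convention; *clusters*
are connected components (≥ 2 members) of the contact graph, with size
defined as the number of member molecules/ions. On top of that:

* per-cluster composition percentages, drug encapsulation probabilities
  P(0), P(≥1), P(≥2) and the percentage of all drugs encapsulated;
* drug/peptide and Zn/peptide ratios, radius of gyration
  R_g = √(⟨|r_i − r̄|²⟩) of the periodically unwrapped cluster;
* Shrake–Rupley SASA burial per component, as 100 ·
  SASA(in cluster) / SASA(isolated);
* mediated triplet motifs (flank–middle–flank labels: PDP, PPD, …, and
  ion-mediated PZP, PZD, DZD, PNP, PND, DND), pairwise kind–kind contact
  probabilities excluding the repulsive Zn²⁺–Zn²⁺ and NO₃⁻–NO₃⁻ pairs,
  per-kind mediation probabilities, and chemical-group contact profiles;
* 16-dimensional per-cluster feature vectors (4 SASA ratios + 12 triplet
  probabilities) and a one-vs-one multiclass linear SVM over them;
* synthetic generators standing in for production trajectories: planted
  clusters with exact ground truth, and a coarse-grained Metropolis Monte
  Carlo co-assembly process with tunable kind-pair affinities
  (nitrate-coordinating, zinc-coordinating or inert drugs);
* multi-model PDB trajectory I/O with a YAML component/group map, and a
  single-config pipeline with a digest-based reproducibility manifest.

The methods vignette (`vignettes/coassembly-methods.Rmd`) documents the
model, the conventions and every numerical choice.

## Worked example

Build the standard +1-drug system (48 peptides, 12 drugs, 48 Zn²⁺ in an
83 Å box — neutralized automatically), run a short Monte Carlo co-assembly
with a nitrate-coordinating drug, and analyze the final frame:

```r
library(coassembly)

comp <- build_composition(48, 12, +1, 48, 83, drug_name = "EPI")
comp
#> System composition (EPI): 48 peptide, 12 drug (q=+1), 48 Zn2+, 96 NO3-, 12 Cl-
#>   cubic box 83.0 Angstrom, net charge 0
initial_drug_peptide_ratio(comp)
#> [1] 0.25

tpl <- default_templates(comp$drug_charge)
aff <- drug_affinity_preset("no3_affine")
frames <- generate_mc_trajectory(comp, tpl, aff, n_sweeps = 500,
                                 sample_every = 100, seed = 1)

clusters <- detect_clusters(frames[[5]], cutoff = 3.5, frame_index = 5)
clusters[[1]]
#> cluster (frame 5): size 33 [PEPTIDE=11, DRUG=2, ZN=8, NO3=12, CL=0], 70 contact edges
round(encapsulation_summary(clusters), 3)
#>  p_no_drug p_ge1_drug p_ge2_drug
#>      0.700      0.300      0.067

st <- cluster_stats(frames[[5]], clusters[[1]], total_drugs = comp$n_drug)
round(st[, c("size", "pct_peptide", "pct_drug", "pct_zn", "pct_no3",
             "rg", "sasa_drug")], 2)
#>   size pct_peptide pct_drug pct_zn pct_no3    rg sasa_drug
#> 1   33       33.33     6.06  24.24   36.36 13.52     51.32

tp <- ensemble_triplet_profile(clusters)
round(tp[tp > 0], 3)
#>   PPP   PDP   PPD   DPD   PZP   PNP   PND   DND
#> 0.113 0.006 0.080 0.002 0.310 0.293 0.072 0.125
```

Reading the numbers: 30 clusters were detected in the frame; 30% of them
contain at least one drug. The largest cluster holds 33 components — 11
peptides, 2 drugs (17% of the system's 12 drug copies), 8 Zn²⁺ and 12
NO₃⁻ — with a 13.5 Å radius of gyration; its drugs retain 51% of their
isolated solvent-accessible surface (about half buried). The triplet
profile is dominated by ion-mediated peptide bridges (PZP, PNP), and
drug-flanked nitrate motifs (PND, DND) outweigh zinc-mediated drug motifs,
as expected for a nitrate-coordinating drug.

The same analysis runs on external multi-model PDB trajectories via
`read_multimodel_pdb()` plus a component map (`load_component_map()`),
through the one-config pipeline `run_pipeline("run.yml")`, or from the
shell via `inst/cli/coassembly.R`.

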
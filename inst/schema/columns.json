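{
  "regionwise.csv": {
    "region_id": "atlas region identifier",
    "contrast": "full | male | female (which subjects enter the treated-vs-control comparison)",
    "measure": "absolute (mm^3) | relative (fraction of subject TBV)",
    "mean_diff": "treated mean minus control mean, in the measure's units",
    "statistic": "Welch (default) or pooled t statistic, treated minus control",
    "df": "degrees of freedom of the test",
    "p": "two-tailed p-value",
    "q": "FDR-adjusted value (bh or two_stage_bky across the regions)",
    "cohens_d": "standardized mean difference, pooled SD, treated minus control",
    "significant_at_q05": "q strictly below the FDR level (default 0.05)"
  },
  "fdr_heatmap.csv": {
    "region_id": "atlas region identifier",
    "direction": "larger | smaller | equal (sign of mean_diff, treated vs control)",
    "q": "FDR-adjusted value",
    "significant": "q strictly below the FDR level"
  },
  "tbv_anova.csv": {
    "F": "one-way ANOVA F across the four sex-by-treatment cells",
    "p": "ANOVA p-value",
    "df1": "numerator degrees of freedom",
    "df2": "denominator degrees of freedom"
  },
  "tbv_pairwise.csv": {
    "contrast": "cell pair, group.sex labels",
    "diff": "difference of cell means (first minus second)",
    "p_adj": "Tukey HSD adjusted p-value"
  },
  "area_effects.csv": {
    "area": "anatomical area name",
    "mean_d": "unweighted mean Cohen's d over the area's regions in the subset",
    "n_regions": "number of regions contributing"
  },
  "block_comparison.csv": {
    "cluster_a": "first covariance cluster of the block",
    "cluster_b": "second covariance cluster (equal to cluster_a for intra-cluster blocks)",
    "n_values": "block r-vector length per group (|a|*|b| Cartesian, or |a|(|a|-1)/2 intra under unique)",
    "mean_treated.M": "mean Pearson r of the block in treated males",
    "mean_treated.F": "mean Pearson r in treated females",
    "mean_control.M": "mean Pearson r in control males",
    "mean_control.F": "mean Pearson r in control females",
    "H": "Kruskal-Wallis statistic across the four groups (tie-corrected)",
    "p": "chi-square p-value on 3 df",
    "q": "FDR-adjusted value across the 21 blocks (two_stage_bky default)",
    "eta_squared": "(H - k + 1) / (n - k), floored at 0",
    "large_effect": "eta_squared strictly greater than 0.14",
    "omnibus_pass": "q below the FDR level AND large_effect",
    "effect_class": "treatment | sex_within_treated | both | none (post-hoc Mann-Whitney classification; none when the omnibus fails)"
  },
  "covariance_<cell>.csv": {
    "<first column>": "region id (matrix row names)",
    "<remaining columns>": "Pearson r of the row region with each column region, across the cell's subjects"
  },
  "brain_behavior.csv": {
    "region_id": "atlas region identifier",
    "measure": "behavioral measure name",
    "stratum": "group.sex cell the correlation is computed within",
    "n": "pairwise-complete sample size",
    "r": "Pearson correlation (NA when not computable)",
    "p": "two-tailed p-value (uncorrected by design)",
    "significant": "p < 0.05, uncorrected",
    "computable": "FALSE when fewer than 3 complete pairs or zero variance"
  },
  "brain_behavior_ordered.csv": {
    "<first column>": "region id, rows ordered by UPGMA on Euclidean distance",
    "<remaining columns>": "stratum:measure r values, columns ordered the same way"
  },
  "volumes.csv": {
    "subject_id": "subject identifier",
    "<region columns>": "absolute regional volume, mm^3",
    "tbv": "optional explicit total brain volume, mm^3 (otherwise TBV = row sum)"
  },
  "design.csv": {
    "subject_id": "subject identifier",
    "sex": "M | F",
    "group": "treated | control"
  },
  "behavior.csv": {
    "subject_id": "subject identifier",
    "<measure columns>": "behavioral values; empty cells are missing (e.g. male-only tasks)"
  },
  "hierarchy.tsv": {
    "region_id": "atlas region identifier",
    "area": "anatomical area (e.g. white matter, cerebral cortex)",
    "cluster": "one of the six covariance clusters, or empty for unassigned"
  },
  "manifest.json": {
    "command": "CLI subcommand",
    "inputs": "path and md5 per input file",
    "options": "all non-path flags, including seed and conventions",
    "version": "covmorph package version",
    "timestamp": "UTC run time"
  },
  "truth.json": {
    "enlargement": "regions, Cohen's d and cells of the simulated enlargement",
    "dimorphism": "regions, delta (SD units, male minus female) and cells",
    "desync": "per desynchronized block: clusters, requested delta_r, cells, and realized post-repair block mean per cell",
    "couplings": "behavioral couplings: measure, region, beta per cell, noise SD",
    "seed": "simulation seed"
  }
}
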
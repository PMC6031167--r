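# hpfold

Ab initio coarse-grained protein structure prediction on the
hydrophobic-polar (HP) lattice model, for people who study lattice protein
folding, benchmark stochastic conformational search, or need a reproducible
HP-model baseline: a two-tier **memetic search** — a constraint-aware
initializer that emits only self-avoiding walks, feeding an
evolutionary-programming loop hybridized with a hill-climbing controller —
on 2D square and triangular lattices.

## The model and the algorithm

The HP model classifies residues as hydrophobic (H) or polar (P) and folds
the chain as a self-avoiding walk (SAW) on a lattice. The free energy counts
hydrophobic contacts:

```
E = − #{ (i, j) : j > i+1, x_i and x_j lattice-adjacent, s_i = s_j = H }
```

Minimizing E is NP-complete, so `hpfold` searches:

* **Tier 1** grows each initial conformation over an occupancy map
  (backtracking out of dead ends), so 100% of the population is SAW-valid —
  no generate-and-discard — with an optional bias that seeds a hydrophobic
  core.
* **Tier 2** is evolutionary programming: one mutation per individual
  (sequence-motif-triggered helix/sheet rewrites, plus corner and pull
  moves), then survivor selection over the parent+offspring pool split 20%
  equal-fitness tournaments / 75% nested-uniform rank selection / 5%
  elitism, with an aging rule for stale elites. A hill-climbing controller
  watches population convergence: a converged population is diversified
  with locally-optimized fresh conformations, a scattered one is refined by
  greedy local search.

An exhaustive enumeration oracle gives exact ground states for short chains,
and the classical benchmark suites (eight square-lattice sequences, eleven
triangular B1–B11, four HP-translated PDB sequences) ship as fixtures with
their reference energies. Both run-length notation dialects used by this
literature (`2H5P…` and `H^2P^5…`) are parsed, and FASTA input is translated
via the fixed H/P residue classes.

## Worked example

```r
library(hpfold)

seq <- hp_sequence("3H2P2(HP)H2P2(HP)H2PH")   # 20-mer benchmark, prefix notation
seq
#> HP sequence: L = 20 , n_H = 10 (H% = 50.0)
#>   HHHPPHPHPHPPHPHPHPPH
#>   from: 3H2P2(HP)H2P2(HP)H2PH

res <- run_search(seq, search_config(seed = 42, target_energy = -10))
res
#> Memetic HP search on square lattice: L = 20
#>  best energy -10 first attained at generation 16 ( 16 generations run )

conformation_energy(res$best$conformation, seq)
#> H-H contacts: 10 (energy -10 )
```

The search reaches −10 — the known ground-state energy of this sequence —
at generation 16 of a single run; `res$best$conformation` holds the move
string and coordinates (`write_conformation_tsv()` saves them), and
`res$history` the per-generation best/mean energies and controller actions.
For short chains the optimum can be certified exactly:

```r
exhaustive_optimum(hp_sequence("HPPH"))
#> $best_energy
#> [1] -1
#> $n_optimal
#> [1] 1
```

Benchmark drivers: `load_benchmarks("square8" | "tri11" | "pdb4")`,
`init_benchmark()` (initializer validity report), `first_tier_benchmark()`
(random vs guided initialization), `fold_benchmarks()` (full search with
restarts). A thin command-line front end lives at `inst/cli/hpfold`
(`fold`, `convert`, `enumerate`, `init-bench`, `bench` subcommands).

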
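---
title: "Memetic search on the HP lattice: model, operators and design choices"
author: "hpfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memetic search on the HP lattice: model, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpfold)
```

## The model

The hydrophobic-polar (HP) model reduces a protein to a string over two
residue classes: hydrophobic (H) and polar (P). A conformation is a
self-avoiding walk (SAW) on a lattice, one residue per site, consecutive
residues on adjacent sites. The driving force of folding is represented by a
single interaction: every pair of H residues that are lattice neighbors but
not sequence neighbors contributes one unit of (negative) free energy,

$$E = -\,\#\{(i,j) : j > i+1,\ \|x_i - x_j\| \in \mathcal{C},\ s_i = s_j = \mathrm{H}\},$$

where $\mathcal{C}$ is the contact neighborhood of the lattice. Minimizing
$E$ (equivalently maximizing the H-H contact count, the *fitness*) drives
hydrophobic residues into a compact core, the coarse analogue of the
hydrophobic collapse. Even in this reduced form, finding the ground state is
NP-complete, which is why the package attacks it with a stochastic,
population-based search.

Two lattices are built in. The `square` lattice has the four moves F, B, U,
D with unit steps $(1,0), (-1,0), (0,1), (0,-1)$. The `tri8` lattice is the
triangular variant in the move-encoding convention this framework uses: the
four square steps plus the diagonals FU $(1,1)$, BU $(-1,1)$, BD $(-1,-1)$,
FD $(1,-1)$, with all eight vectors also acting as contact directions. A
`tri6` lattice (square steps plus $(1,1)$ and $(-1,-1)$ only) is provided
because much of the published triangular-lattice literature assumes
six-coordination; energies on `tri8` are systematically lower (more contact
slots per site), so cross-study comparisons must name the lattice
explicitly.

A conformation is stored as a *relative move string* of $L-1$ symbols.
Residues 1 and 2 are anchored at $(0,0)$ and $(1,0)$, so the first move is
always F; this removes the translational and most of the rotational
degeneracy. The remaining reflection is removed where it matters -- in the
exhaustive enumerator and in `canonical_conformation()` -- by orienting the
first vertical deviation upward, so every rotation/reflection class of a
structure has exactly one canonical encoding (the genotype-phenotype map is
bijective on canonical strings).

## Sequence input

Benchmark sequences in this literature are printed in two run-length
dialects, both of which `parse_hp_notation()` accepts: a *prefix* dialect in
which a number multiplies the following symbol or parenthesized group
("`2H5P...`", used by the square-lattice suite) and a *caret* dialect with
exponents ("`H^2P^2(HP^2)^6...`", used by the triangular suite). Dialect
auto-detection keys on the presence of `^`. Amino-acid sequences are mapped
to HP strings by a fixed residue partition, H = {A, G, I, L, M, F, P, W, V},
P = {R, N, D, C, E, Q, H, K, S, T, Y}. Note the two deliberate oddities of
that partition -- proline counts as hydrophobic and histidine as polar; the
partition is kept exactly as the benchmark suite defines it (a custom map
can be passed to `fasta_to_hp()`).

## Tier 1: constraint-aware initialization

Uniformly random move strings almost never survive the SAW constraint once
chains get long (validity decays roughly like $(\mu/k)^{L}$ with $\mu$ the
lattice connective constant), so a naive generate-and-discard initializer
wastes nearly all of its work. The guided initializer
(`guided_conformation()`) instead grows the chain over an occupancy map:
each extension draws among the currently *free* neighbor sites, and a dead
end (no free neighbor) is resolved by stepping back one residue and
re-randomizing. Every emitted conformation is a SAW by construction -- this
is a structural guarantee, tested at scale, not a statistical tendency.

When the residue being placed is hydrophobic, with probability `h_bias`
(default 0.5) the draw prefers free sites already in contact with a placed H
residue. This is the operational form of the "fold toward a hydrophobic
core" heuristic; it measurably raises the initial population's best contact
count relative to the random baseline on every packaged benchmark.

## Tier 2: evolutionary programming with a hill-climbing controller

The search is evolutionary programming: mutation is the only variation
operator (no crossover), and selection works on a parent+offspring pool.
One generation of `step_generation()` does:

1. **Variation.** Every individual produces one offspring by a single
   mutation attempt; an attempt that would violate the SAW constraint (or
   the anchor) is rejected and the parent stands in. Feasibility is the only
   acceptance requirement -- quality is selection's job.
2. **Selection** over the combined pool of $2n$ individuals, partitioned
   20% / 75% / 5%:
   * *Elitism* (5%): the best pool members survive unchanged; their age
     counters increment while they stay elite.
   * *Tournament* (20%): an equal-fitness group of up to `tournament_size`
     pool members (seeded by a rank draw) receives the *same* mutation, and
     the member whose probe offspring scores best survives.
   * *Rank-based* (75%): survivors drawn by the nested-uniform rule --
     $m \sim U\{1..2n\}$, then position $\sim U\{1..m\}$ on the
     fitness-sorted pool -- which gives position $i$ probability
     $\frac{1}{2n}\sum_{m \ge i} 1/m$, strictly decreasing but far from
     winner-takes-all. These draws are made *without* replacement, so
     multiple copies of one individual can only arise through elitism and
     tournaments; with replacement the population collapses onto the top
     fitness class within a couple of generations and exploration dies.

   An exponential rank weighting $1 - e^{-f_r/\beta}$ (reversed rank
   $f_r$, $\beta = n/3$) is available as `rank_select(mode = "weighted")`.
   As printed in the source literature the weighting assigns the *best*
   individual probability zero; with the rank reversed it matches the
   stated intent, but the nested-uniform rule is the operative selector.

3. **Hill-climbing controller** (`hc_controller()`): watches the share of
   the population sitting on the modal energy. At or above 0.70 the
   population has converged and the controller *diversifies*: 30% of the
   non-elite individuals are replaced by fresh guided conformations, each
   refined by a greedy local search (random corner/pull proposals, budget
   $10L$ trials, equal-energy moves allowed so the walk can cross plateaus)
   before it enters the population. The search is therefore an iterated
   local search across basins once the population converges, which is what
   makes the hardest benchmarks (unique ground states) reachable. At or
   below 0.10 the population is too scattered and the controller
   *intensifies*: every individual gets a strictly greedy local search
   (improvements only, budget $2L$), which never decreases any fitness.
4. **Aging** (`age_and_cull()`): an individual that has been elite for 25
   consecutive generations without improving is stale; within each
   equal-fitness group of aged individuals a tournament keeps one survivor
   and replaces the rest with fresh guided conformations.

A run stops at the generation budget, when a caller-supplied target energy
is reached, or after `stagnation_window` generations without a new best.
`run_search()` records a per-generation history (best, mean, modal share,
controller action) and the generation $G_c$ at which the final best energy
was first attained; everything is bit-reproducible from the seed, because
every random draw in both the R and the compiled layer goes through R's RNG
stream.

## Mutation operators

* **Corner move**: residue $i$ in a bend flips across the parallelogram
  spanned by its two bonds, if the opposite site is free.
* **Pull move**: residue $i$ relocates to a free site adjacent to residue
  $i+1$, and preceding residues are dragged along the vacated positions
  until the chain reconnects; chain ends simply relocate to a free neighbor
  of their single neighbor. Both directions are implemented (the tail-ward
  variant operates on the reversed chain), giving the standard bidirectional
  pull neighborhood, which is ergodic enough that a non-worsening pull walk
  alone reaches exhaustive optima on short chains (a property the test suite
  checks).
* **Motif operators**, triggered by sequence patterns: the substring
  `PPHPPHPP` selects a *downward helix*, `HPPHHPPH` an *upward helix*, and a
  run of three or more identical residues a *sheet*. The helix rewrite is
  the tight width-2 serpentine (move cycle D,F,U,F downward / U,F,D,F
  upward; FD/FU diagonal analogues on `tri8`), chosen because it brings the
  pattern's H residues into lattice contact; the sheet rewrite extends the
  run straight along its entering direction. Pattern matching happens on the
  expanded residue string (the only well-defined choice), scanning left to
  right without overlaps, helix patterns taking precedence over a sheet run
  starting at the same position.

Mutation dispatch: with probability `motif_prob` (default 0.2) a random
motif site's operator is applied, otherwise a corner or pull move at a
random index. A grid check (0, 0.1, 0.3, 0.5) showed benchmark success to be
insensitive to this parameter; 0.2 keeps motif rewrites frequent enough to
seed secondary-structure-like segments without drowning the chain moves.
Operators never rewrite the anchored first bond; a proposal that moves the
anchor is accepted only if a pure lattice rotation restores it (always
possible on the square lattice, not for a diagonal first bond on `tri8`).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `population_size` | 100 | conformations per generation (the benchmark experiments all use 100; 200 is the other value the source work cites) |
| `max_generations` | 500 | generation budget per run |
| `stagnation_window` | 150 | stop after this many generations without a new best |
| `tournament_fraction` | 0.20 | selection share via equal-fitness tournaments |
| `rank_fraction` | 0.75 | selection share via nested-uniform rank draws |
| `elite_fraction` | 0.05 | elitist share |
| `aging_limit` | 25 | elite age triggering the aging tournament |
| `hc_convergence_threshold` | 0.70 | modal share at which the controller diversifies |
| `hc_diversity_threshold` | 0.10 | modal share at which it intensifies |
| `hc_diversify_fraction` | 0.30 | non-elite fraction replaced on diversify |
| `motif_prob` | 0.2 | probability of a motif operator per mutation |
| `h_bias` | 0.5 | hydrophobic-core bias of the guided initializer |

## Numerical and degenerate-input choices

* Energies are non-positive integers; fitness is their negation. Ties in
  sorting are broken stably by index, so runs are deterministic.
* An all-P sequence has energy 0 in every conformation; the search reports 0
  at generation 0.
* `convergence_rate(e, e_star)` is
  $(1 - |E - E^*|/|E^*|) \times 100$, is not clamped below, and refuses
  $E^* = 0$.
* The exhaustive enumerator refuses chains beyond a guard length (16 square,
  12 triangular by default): it is an oracle for short chains, not a solver.
* Digit-to-move conventions in the source literature are inconsistent
  between sections; this package fixes one convention (codes $0..k-1$ in
  alphabet order F, B, U, D, FU, BU, BD, FD) and never exposes raw digits.
* Occupancy is tracked by a constant-time stamped hash of coordinates
  rather than a fixed $L \times L$ flag array, so pull moves can temporarily
  wander anywhere without bounds issues.

## What the tests do and do not show

The test suite checks the machinery against independent oracles: energies
against brute-force pair enumeration, the search optimum against exhaustive
enumeration on random chains of up to 10 residues (20 sequences, 3 seeds
each), the initializer's SAW guarantee at 1000 draws per benchmark, SAW
preservation over 10^4 chained random mutations, and the nested-uniform
selector against its closed form at 10^5 draws. The benchmark checks run
the full search at population 100 for up to 500 generations with up to
20 restarts (50 for the 36-mer) and verify that the published reference
energies are attained; the oracle-equivalence runs use population 50 and 80
generations, sizes chosen so the whole suite completes in a few minutes.

Passing these tests shows the algorithm does what this document says on
*hypothetical HP benchmark strings and HP-translated PDB sequences*. It does
not show anything about real protein energetics: the HP model has no side
chains, no backbone geometry, and a one-parameter contact potential, and a
2D lattice under-coordinates every residue relative to 3D packing. Energies
on `tri8` are not comparable to six-coordination triangular results.

## Known limitations

* With the diversity threshold at its default 0.10, the intensify branch is
  effectively unreachable for short chains: a population spread over at
  most ~10 discrete energy levels keeps the modal share above 0.10. The
  memetic refinement of short-chain searches therefore happens inside the
  diversify action (refined injections), which is also where it proved to
  matter empirically.
* The aging tournament resets the survivor's age, giving a stale elite a
  fresh lease rather than discarding it outright; an elite that truly sits
  in a local optimum is eventually displaced by refined injections instead.
* Long-sequence benchmarks (85-100 residues, and the PDB translations) are
  out of desk-verification reach: the package folds them, but no exact
  reference exists to certify optimality, and the packaged reference
  energies for them are reported search results, not proven ground states.
* Head-end moves are slightly restricted on the triangular lattice (a
  proposal that leaves a diagonal first bond is rejected); tail-end moves
  are unrestricted, and no effect on attainable energies has been observed
  on the benchmarks.
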
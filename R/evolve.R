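# Tier-2 search driver: selection operators, hill-climbing controller,
# evolutionary-programming generation loop, stopping rules, convergence
# metrics.

#' Search configuration
#'
#' Parameters of the memetic search. Selection effort is partitioned into
#' tournament (20%), rank-based (75%) and elitist (5%) shares; the
#' hill-climbing controller watches the share of the population sitting on
#' the modal energy and either diversifies (share >= 0.70: a fraction of
#' non-elite individuals is replaced by fresh guided conformations) or
#' intensifies (share <= 0.10: greedy local search, budget `2 * L` trials
#' per individual). Elites that fail to improve for `aging_limit`
#' consecutive generations face a replacement tournament.
#'
#' @param population_size number of conformations (>= 4).
#' @param max_generations generation budget.
#' @param stagnation_window stop after this many generations without a new
#'   best energy.
#' @param tournament_fraction,rank_fraction,elite_fraction selection shares;
#'   must sum to 1.
#' @param tournament_size equal-fitness pool size for tournaments; defaults
#'   to `tournament_fraction * population_size`.
#' @param aging_limit elite age (generations) that triggers the aging
#'   tournament.
#' @param hc_convergence_threshold modal-energy share at or above which the
#'   controller diversifies.
#' @param hc_diversity_threshold modal-energy share at or below which the
#'   controller intensifies.
#' @param hc_diversify_fraction fraction of non-elite individuals replaced on
#'   a diversify action.
#' @param motif_prob probability that a mutation uses a motif operator when
#'   the sequence has motif sites.
#' @param h_bias hydrophobic-core bias of the guided initializer.
#' @param init_method `"guided"` or `"random"` initial population.
#' @param lattice lattice name.
#' @param target_energy optional stop threshold: the search halts once the
#'   best energy is at or below it.
#' @param seed optional integer seed; the whole run is reproducible from it.
#' @return list of class `hp_search_config`.
#' @export
search_config <- function(population_size = 100L,
                          max_generations = 500L,
                          stagnation_window = 150L,
                          tournament_fraction = 0.20,
                          rank_fraction = 0.75,
                          elite_fraction = 0.05,
                          tournament_size = NULL,
                          aging_limit = 25L,
                          hc_convergence_threshold = 0.70,
                          hc_diversity_threshold = 0.10,
                          hc_diversify_fraction = 0.30,
                          motif_prob = 0.2,
                          h_bias = 0.5,
                          init_method = c("guided", "random"),
                          lattice = "square",
                          target_energy = NULL,
                          seed = NULL) {
  stopifnot(population_size >= 4,
            abs(tournament_fraction + rank_fraction + elite_fraction - 1) < 1e-9,
            hc_convergence_threshold > 0, hc_convergence_threshold < 1,
            hc_diversity_threshold > 0,
            hc_diversity_threshold < hc_convergence_threshold)
  if (is.null(tournament_size))
    tournament_size <- max(1L, round(tournament_fraction * population_size))
  if (tournament_size >= population_size)
    stop("tournament_size must be smaller than population_size")
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 stagnation_window = as.integer(stagnation_window),
                 tournament_fraction = tournament_fraction,
                 rank_fraction = rank_fraction,
                 elite_fraction = elite_fraction,
                 tournament_size = as.integer(tournament_size),
                 aging_limit = as.integer(aging_limit),
                 hc_convergence_threshold = hc_convergence_threshold,
                 hc_diversity_threshold = hc_diversity_threshold,
                 hc_diversify_fraction = hc_diversify_fraction,
                 motif_prob = motif_prob,
                 h_bias = h_bias,
                 init_method = match.arg(init_method),
                 lattice = lattice,
                 target_energy = target_energy,
                 seed = seed),
            class = "hp_search_config")
}

#' Rank-based parent selection
#'
#' The operative selector is the nested-uniform draw: a bound `m` is drawn
#' uniformly on `{1..n}` and the selected rank uniformly on `{1..m}`, so the
#' probability of (1-based) sorted position `i` is
#' `P(i) = (1/n) * sum_{m=i..n} 1/m`, strictly decreasing in rank without
#' letting the best individual dominate. `mode = "weighted"` instead samples
#' proportionally to `1 - exp(-f_r / beta)` with the *reversed* rank
#' `f_r = n - i` (best individual has the largest weight) and normalization
#' constant `beta` (default `n/3`).
#'
#' @param n population size (individuals assumed sorted by decreasing
#'   fitness, best first).
#' @param mode `"nested"` (default) or `"weighted"`.
#' @param beta normalization constant for the weighted mode.
#' @return 1-based index into the fitness-sorted order.
#' @export
rank_select <- function(n, mode = c("nested", "weighted"), beta = NULL) {
  stopifnot(n >= 1)
  mode <- match.arg(mode)
  if (mode == "nested") {
    m <- sample.int(n, 1L)
    return(sample.int(m, 1L))
  }
  if (is.null(beta)) beta <- n / 3
  w <- 1 - exp(-(n - seq_len(n)) / beta)
  if (all(w == 0)) w <- rep(1, n)
  sample.int(n, 1L, prob = w)
}

#' Tournament selection over an equal-fitness pool
#'
#' Every member of the pool receives the *same* mutation (one operator
#' specification drawn once); the member whose offspring scores best is
#' returned, ties resolved by pool order. Used on the equal-fitness share of
#' the population and in the aging operator.
#'
#' @param pop an `hp_population`.
#' @param seq the matching [hp_sequence()].
#' @param members indices of the equal-fitness pool (defaults to all).
#' @param motif_prob motif-operator probability, as in
#'   [mutate_conformation()].
#' @return list with `winner` (index into `pop`), `offspring`
#'   (an `hp_mutation` for the winner) and `energies` (offspring energy per
#'   member, `NA` where rejected).
#' @export
tournament_select <- function(pop, seq, members = seq_len(pop$size),
                              motif_prob = 0.2) {
  seq <- hp_sequence(seq)
  if (!length(members)) stop("empty tournament pool")
  if (length(unique(pop$energy[members])) > 1L)
    stop("tournament pool must have equal fitness")
  sites <- find_motif_sites(seq)
  lat <- lattice_spec(pop$lattice)
  L <- seq$length
  # one operator specification, applied to every member
  if (nrow(sites) > 0 && runif(1) < motif_prob) {
    s <- sites[sample.int(nrow(sites), 1L), ]
    spec <- list(kind = .op_kinds[[s$kind]], index = -1L,
                 mstart = s$start - 1L, span = s$span, label = s$kind)
  } else if (runif(1) < 0.5 && L >= 3) {
    spec <- list(kind = .op_kinds[["corner"]],
                 index = sample.int(L - 2L, 1L), mstart = -1L, span = 0L,
                 label = "corner")
  } else {
    spec <- list(kind = .op_kinds[["pull"]],
                 index = sample.int(L, 1L) - 1L, mstart = -1L, span = 0L,
                 label = "pull")
  }
  isH <- seq$residues == "H"
  energies <- rep(NA_integer_, length(members))
  results <- vector("list", length(members))
  for (k in seq_along(members)) {
    res <- cpp_try_op(pop$codes[members[k], ], isH, lat$id,
                      spec$kind, spec$index, spec$mstart, spec$span)
    results[[k]] <- res
    if (res$accepted) energies[k] <- res$energy
  }
  win <- if (all(is.na(energies))) 1L else which.min(energies)
  parent <- conformation_from_codes(pop$codes[members[win], ], lat)
  list(winner = members[win],
       offspring = new_mutation_result(parent, seq, results[[win]],
                                       spec$label),
       energies = energies)
}

#' Advance the population by one generation
#'
#' One evolutionary-programming step in two phases. Variation: every
#' individual produces one offspring by a single mutation attempt (a
#' rejected attempt leaves a parent copy standing in). Selection over the
#' combined parent + offspring pool, the best individuals making multiple
#' copies while the rest are discarded: the elite share is carried unchanged
#' (ages incremented); the tournament share is filled by winners of
#' same-mutation probes over equal-fitness groups; the rank share by
#' nested-uniform draws over the fitness-sorted pool (without replacement,
#' so copies arise only through elitism and tournaments). Population size is
#' preserved exactly and every individual remains SAW-valid.
#'
#' @param pop an `hp_population`.
#' @param seq the matching [hp_sequence()].
#' @param config an [search_config()].
#' @param sites precomputed motif sites (optional).
#' @return the next `hp_population`, with attribute `op_stats` (usage and
#'   acceptance counts per operator).
#' @export
step_generation <- function(pop, seq, config = search_config(),
                            sites = NULL) {
  seq <- hp_sequence(seq)
  lat <- lattice_spec(pop$lattice)
  if (is.null(sites)) sites <- find_motif_sites(seq)
  res <- cpp_generation(pop$codes, pop$energy, pop$age,
                        seq$residues == "H", lat$id, motif_matrix(sites),
                        config$motif_prob, config$elite_fraction,
                        config$tournament_fraction, config$tournament_size)
  out <- new_population(res$pop, res$energy, res$age, lat, pop$L)
  stats <- data.frame(operator = names(.op_kinds),
                      proposed = res$op_count, accepted = res$op_accept)
  attr(out, "op_stats") <- stats
  out
}

#' Hill-climbing controller decision
#'
#' Computes the share of the population sitting on the modal energy value.
#' At or above `hc_convergence_threshold` the population has converged and
#' the controller orders diversification; at or below
#' `hc_diversity_threshold` it is too diverse and local search
#' (intensification) is ordered; otherwise no action.
#'
#' @param pop an `hp_population`.
#' @param config an [search_config()].
#' @return `"diversify"`, `"intensify"` or `"none"`, with the modal share as
#'   attribute `mode_share`.
#' @export
hc_controller <- function(pop, config = search_config()) {
  share <- max(table(pop$energy)) / pop$size
  action <- if (share >= config$hc_convergence_threshold) "diversify"
  else if (share <= config$hc_diversity_threshold) "intensify"
  else "none"
  attr(action, "mode_share") <- as.numeric(share)
  action
}

#' Apply a hill-climbing controller action
#'
#' `"diversify"` replaces a random `hc_diversify_fraction` of the non-elite
#' individuals with fresh guided conformations; `"intensify"` runs a greedy
#' local search (random corner/pull proposals, improvements only, budget
#' `2 * L` trials) on every individual, which never decreases any fitness;
#' `"none"` returns the population unchanged.
#'
#' @inheritParams step_generation
#' @param action a [hc_controller()] decision.
#' @return the updated `hp_population`.
#' @export
apply_hc_action <- function(pop, seq, action, config = search_config(),
                            sites = NULL) {
  if (action == "none") return(pop)
  seq <- hp_sequence(seq)
  lat <- lattice_spec(pop$lattice)
  isH <- seq$residues == "H"
  if (action == "diversify") {
    if (is.null(sites)) sites <- find_motif_sites(seq)
    mm <- motif_matrix(sites)
    n_elite <- max(1L, round(config$elite_fraction * pop$size))
    non_elite <- order(pop$energy)[-seq_len(n_elite)]
    n_rep <- floor(config$hc_diversify_fraction * length(non_elite))
    if (n_rep > 0) {
      idx <- sample(non_elite, n_rep)
      for (i in idx) {
        fresh <- cpp_guided(isH, lat$id, config$h_bias)
        # the injected conformation is itself hill-climbed before it enters
        # the population (iterated local search across fresh basins);
        # equal-energy moves are allowed so the walk can cross plateaus
        ls <- cpp_local_search(fresh, isH, lat$id, 10L * pop$L, mm,
                               config$motif_prob, TRUE)
        pop$codes[i, ] <- ls$moves
        pop$energy[i] <- ls$energy
        pop$age[i] <- 0L
      }
    }
    return(pop)
  }
  # intensify: greedy local search on each individual
  if (is.null(sites)) sites <- find_motif_sites(seq)
  mm <- motif_matrix(sites)
  budget <- 2L * pop$L
  for (i in seq_len(pop$size)) {
    ls <- cpp_local_search(pop$codes[i, ], isH, lat$id, budget, mm,
                           config$motif_prob)
    pop$codes[i, ] <- ls$moves
    pop$energy[i] <- ls$energy
  }
  pop
}

#' Aging operator
#'
#' Individuals that have been elite for `aging_limit` consecutive
#' generations without improving are aged: within each equal-fitness group
#' of aged individuals a tournament is held, the winner keeps its place
#' (age reset), and the losers are replaced by fresh guided conformations.
#'
#' @inheritParams step_generation
#' @return the updated `hp_population`.
#' @export
age_and_cull <- function(pop, seq, config = search_config()) {
  aged <- which(pop$age >= config$aging_limit)
  if (!length(aged)) return(pop)
  seq <- hp_sequence(seq)
  lat <- lattice_spec(pop$lattice)
  isH <- seq$residues == "H"
  for (e in unique(pop$energy[aged])) {
    grp <- aged[pop$energy[aged] == e]
    win <- if (length(grp) == 1L) grp
    else tournament_select(pop, seq, grp, config$motif_prob)$winner
    pop$age[win] <- 0L
    losers <- setdiff(grp, win)
    for (i in losers) {
      pop$codes[i, ] <- cpp_guided(isH, lat$id, config$h_bias)
      pop$age[i] <- 0L
    }
    if (length(losers))
      pop$energy[losers] <- cpp_energy_batch(
        pop$codes[losers, , drop = FALSE], isH, lat$id)
  }
  pop
}

#' Run the memetic search
#'
#' Full two-tier run: guided (or random) initialization, then the
#' evolutionary-programming loop (generation step, hill-climbing controller,
#' aging) until the generation budget, the target energy, or the stagnation
#' window is reached. Fully reproducible from `config$seed`.
#'
#' @param seq an [hp_sequence()].
#' @param config an [search_config()].
#' @return an object of class `hp_search_result`: `best` (individual with
#'   conformation and energy), `best_energy`, `g_c` (generation at which the
#'   best energy was first attained), `history` (per-generation best / mean
#'   energy, modal share, controller action) and `config`.
#' @export
run_search <- function(seq, config = search_config()) {
  seq <- hp_sequence(seq)
  if (!is.null(config$seed)) set.seed(config$seed)
  lat <- lattice_spec(config$lattice)
  sites <- find_motif_sites(seq)
  init <- build_population(seq, lat, size = config$population_size,
                           method = config$init_method,
                           h_bias = config$h_bias)
  pop <- init$population

  gmax <- config$max_generations
  hist_best <- integer(gmax + 1L)
  hist_mean <- numeric(gmax + 1L)
  hist_share <- numeric(gmax + 1L)
  hist_action <- character(gmax + 1L)

  best <- min(pop$energy)
  best_codes <- pop$codes[which.min(pop$energy), ]
  g_c <- 0L
  hist_best[1] <- best
  hist_mean[1] <- mean(pop$energy)
  hist_share[1] <- attr(hc_controller(pop, config), "mode_share")
  hist_action[1] <- "init"
  g <- 0L

  while (g < gmax) {
    if (!is.null(config$target_energy) && best <= config$target_energy) break
    if (g - g_c >= config$stagnation_window) break
    g <- g + 1L
    pop <- step_generation(pop, seq, config, sites)
    action <- hc_controller(pop, config)
    pop <- apply_hc_action(pop, seq, action, config, sites)
    pop <- age_and_cull(pop, seq, config)
    if (min(pop$energy) < best) {
      best <- min(pop$energy)
      best_codes <- pop$codes[which.min(pop$energy), ]
      g_c <- g
    }
    hist_best[g + 1L] <- best
    hist_mean[g + 1L] <- mean(pop$energy)
    hist_share[g + 1L] <- attr(action, "mode_share")
    hist_action[g + 1L] <- as.character(action)
  }

  history <- data.frame(generation = 0:g,
                        best = hist_best[1:(g + 1L)],
                        mean = hist_mean[1:(g + 1L)],
                        mode_share = hist_share[1:(g + 1L)],
                        action = hist_action[1:(g + 1L)])
  best_conf <- conformation_from_codes(best_codes, lat)
  structure(list(best = list(conformation = best_conf, energy = best,
                             fitness = -best),
                 best_energy = best,
                 g_c = g_c,
                 generations = g,
                 history = history,
                 final_population = pop,
                 config = config,
                 seq = seq),
            class = "hp_search_result")
}

#' @export
print.hp_search_result <- function(x, ...) {
  cat("Memetic HP search on", x$config$lattice, "lattice: L =",
      x$seq$length, "\n best energy", x$best_energy,
      "first attained at generation", x$g_c,
      "(", x$generations, "generations run )\n")
  invisible(x)
}

#' Fold a sequence with restarts
#'
#' Runs [run_search()] up to `restarts` times with seeds
#' `seed, seed + 1, ...`, stopping early once `target_energy` is reached,
#' and returns the best run.
#'
#' @param seq an [hp_sequence()].
#' @param config base [search_config()]; its seed is overridden per restart.
#' @param restarts maximum number of independent runs.
#' @param seed base seed.
#' @param target_energy optional early-stop energy (also passed to each
#'   run).
#' @return list with `best_energy`, `g_c`, `best` (conformation), `runs`
#'   (data.frame with one row per restart) and `n_runs`.
#' @export
fold_sequence <- function(seq, config = search_config(), restarts = 20L,
                          seed = 1L, target_energy = NULL) {
  seq <- hp_sequence(seq)
  if (!is.null(target_energy)) config$target_energy <- target_energy
  best <- NULL
  runs <- data.frame()
  for (r in seq_len(restarts)) {
    config$seed <- seed + r - 1L
    res <- run_search(seq, config)
    runs <- rbind(runs, data.frame(restart = r, seed = config$seed,
                                   best_energy = res$best_energy,
                                   g_c = res$g_c,
                                   generations = res$generations))
    if (is.null(best) || res$best_energy < best$best_energy) best <- res
    if (!is.null(config$target_energy) &&
        best$best_energy <= config$target_energy) break
  }
  list(best_energy = best$best_energy, g_c = best$g_c,
       best = best$best, runs = runs, n_runs = nrow(runs))
}

#' Convergence rate relative to a reference optimum
#'
#' `(1 - |E - E*| / |E*|) * 100`: the percentage closeness of an achieved
#' energy to a reference optimum (100 when the optimum is attained; not
#' clamped below).
#'
#' @param e achieved energy.
#' @param e_star reference optimum (non-zero).
#' @return percentage.
#' @examples
#' convergence_rate(-8, -9) # 88.9
#' @export
convergence_rate <- function(e, e_star) {
  if (any(e_star == 0)) stop("reference optimum must be non-zero")
  (1 - abs(e - e_star) / abs(e_star)) * 100
}
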
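test_that("search configuration validates its invariants", {
  expect_error(search_config(population_size = 2), "population_size")
  expect_error(search_config(tournament_fraction = 0.5))
  expect_error(search_config(hc_convergence_threshold = 1.2))
  expect_error(search_config(population_size = 10, tournament_size = 10),
               "tournament_size")
  cfg <- search_config()
  expect_equal(cfg$tournament_fraction + cfg$rank_fraction +
                 cfg$elite_fraction, 1)
  expect_equal(cfg$tournament_size, 20L)
})

test_that("nested-uniform rank selection matches its closed form", {
  expect_equal(rank_select(1), 1L)
  set.seed(121)
  n <- 2
  draws <- vapply(1:20000, function(i) rank_select(n), integer(1))
  expect_equal(mean(draws == 1L), 0.75, tolerance = 0.02)
  # P(i) = (1/n) * sum_{m=i..n} 1/m, monotone decreasing in rank
  n <- 10
  draws <- vapply(1:50000, function(i) rank_select(n), integer(1))
  freq <- tabulate(draws, n) / length(draws)
  closed <- vapply(1:n, function(i) sum(1 / (i:n)) / n, numeric(1))
  expect_equal(freq, closed, tolerance = 0.05)
  expect_true(all(diff(freq) < 0.02))
})

test_that("exponential rank weighting favors the best individual", {
  set.seed(122)
  draws <- vapply(1:20000, function(i) rank_select(20, mode = "weighted"),
                  integer(1))
  freq <- tabulate(draws, 20)
  expect_gt(freq[1], freq[10])
  expect_gt(freq[10], freq[20])
})

test_that("tournament selection applies one shared mutation and returns the best member", {
  set.seed(131)
  s <- hp_sequence("2H2P6(H2P)2H")
  pop <- build_population(s, size = 20)$population
  # singleton pool: that individual wins
  i <- which.min(pop$energy)[1]
  res <- tournament_select(pop, s, members = i)
  expect_equal(res$winner, i)
  # pools must have equal fitness
  if (length(unique(pop$energy)) > 1) {
    mixed <- c(which.min(pop$energy)[1], which.max(pop$energy)[1])
    expect_error(tournament_select(pop, s, members = mixed), "equal fitness")
  }
  grp <- which(pop$energy == pop$energy[i])
  set.seed(5); a <- tournament_select(pop, s, members = grp)
  set.seed(5); b <- tournament_select(pop, s, members = grp)
  expect_identical(a$winner, b$winner)
  expect_identical(a$energies, b$energies)
})

test_that("a generation preserves population size, validity and the best energy", {
  set.seed(141)
  s <- hp_sequence("PH2PHP3HP2HP5H")
  cfg <- tiny_config()
  pop <- build_population(s, size = cfg$population_size)$population
  best <- min(pop$energy)
  for (g in 1:25) {
    pop <- step_generation(pop, s, cfg)
    expect_equal(pop$size, cfg$population_size)
    # recomputing energies errors if any individual were non-SAW
    expect_identical(
      as.integer(pop$energy),
      as.integer(hpfold:::cpp_energy_batch(pop$codes, s$residues == "H", 0L)))
    expect_lte(min(pop$energy), best)   # elitism: best never degrades
    best <- min(pop$energy)
  }
  stats <- attr(pop, "op_stats")
  expect_equal(sum(stats$proposed), cfg$population_size)
  expect_true(all(stats$accepted <= stats$proposed))
})

test_that("selection shares partition the population within rounding", {
  cfg <- search_config()
  n <- cfg$population_size
  n_e <- max(1, round(cfg$elite_fraction * n))
  n_t <- round(cfg$tournament_fraction * n)
  expect_equal(n_e, 5)
  expect_equal(n_t, 20)
  expect_equal(n - n_e - n_t, 75)
})

test_that("elite ages increment while they persist", {
  set.seed(151)
  s <- hp_sequence("3H2P2(HP)H2P2(HP)H2PH")
  cfg <- tiny_config(motif_prob = 0)
  pop <- build_population(s, size = cfg$population_size)$population
  for (g in 1:5) pop <- step_generation(pop, s, cfg)
  expect_gte(max(pop$age), 1L)
})

test_that("the controller diversifies converged and intensifies scattered populations", {
  fake <- function(energies) {
    structure(list(energy = energies, size = length(energies)),
              class = "hp_population")
  }
  cfg <- search_config()
  a <- hc_controller(fake(rep(-5L, 100)), cfg)
  expect_equal(as.character(a), "diversify")
  expect_equal(attr(a, "mode_share"), 1)
  b <- hc_controller(fake(-(1:100)), cfg)
  expect_equal(as.character(b), "intensify")
  c <- hc_controller(fake(c(rep(-5L, 40), -(1:60))), cfg)
  expect_equal(as.character(c), "none")
})

test_that("intensification never decreases any individual's fitness", {
  set.seed(161)
  s <- hp_sequence("2PH2P3(2H4P)2H")
  pop <- build_population(s, size = 30)$population
  before <- pop$energy
  after <- apply_hc_action(pop, s, "intensify", search_config())
  expect_true(all(after$energy <= before))
  expect_identical(
    as.integer(after$energy),
    as.integer(hpfold:::cpp_energy_batch(after$codes, s$residues == "H", 0L)))
})

test_that("diversification keeps the elite and injects valid conformations", {
  set.seed(162)
  s <- hp_sequence("2PH2P3(2H4P)2H")
  pop <- build_population(s, size = 30)$population
  best <- min(pop$energy)
  after <- apply_hc_action(pop, s, "diversify", search_config())
  expect_equal(after$size, pop$size)
  expect_lte(min(after$energy), best)
  expect_identical(
    as.integer(after$energy),
    as.integer(hpfold:::cpp_energy_batch(after$codes, s$residues == "H", 0L)))
  expect_identical(apply_hc_action(pop, s, "none", search_config()), pop)
})

test_that("aging replaces stale equal-fitness elites except one survivor", {
  set.seed(171)
  s <- hp_sequence("2H2P6(H2P)2H")
  cfg <- search_config()
  pop <- build_population(s, size = 12)$population
  expect_identical(age_and_cull(pop, s, cfg), pop)  # nobody aged
  # force everyone into one aged equal-fitness class
  i <- which.min(pop$energy)[1]
  for (j in seq_len(pop$size)) pop$codes[j, ] <- pop$codes[i, ]
  pop$energy <- rep(pop$energy[i], pop$size)
  pop$age <- rep(cfg$aging_limit, pop$size)
  culled <- age_and_cull(pop, s, cfg)
  expect_equal(culled$size, pop$size)
  expect_true(all(culled$age == 0L))
  # exactly one member of the class survives unchanged
  same <- vapply(seq_len(culled$size), function(j)
    all(culled$codes[j, ] == pop$codes[i, ]), logical(1))
  expect_gte(sum(same), 1L)
  expect_lt(sum(same), pop$size)
  expect_identical(
    as.integer(culled$energy),
    as.integer(hpfold:::cpp_energy_batch(culled$codes, s$residues == "H", 0L)))
})

test_that("an all-polar sequence folds to zero energy immediately", {
  res <- run_search(hp_sequence(strrep("P", 12)),
                    tiny_config(max_generations = 5L, seed = 2))
  expect_equal(res$best_energy, 0L)
  expect_equal(res$g_c, 0L)
})

test_that("searches are bit-reproducible from the seed", {
  s <- hp_sequence("HPHP3H3P4H2P2H")
  cfg <- tiny_config(seed = 77)
  a <- run_search(s, cfg)
  b <- run_search(s, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$best_energy, b$best_energy)
  expect_identical(a$best$conformation$moves, b$best$conformation$moves)
})

test_that("the search matches the exhaustive oracle on short chains", {
  set.seed(181)
  for (str in c("HHPHHPPH", "HPHHPPHHH")) {
    s <- hp_sequence(str)
    opt <- exhaustive_optimum(s)$best_energy
    cfg <- tiny_config(seed = 9, target_energy = opt)
    expect_equal(run_search(s, cfg)$best_energy, opt)
  }
})

test_that("the best-so-far trace is monotone and g_c marks its first attainment", {
  s <- hp_sequence("2H2P6(H2P)2H")
  res <- run_search(s, tiny_config(seed = 31))
  expect_true(all(diff(res$history$best) <= 0))
  expect_equal(min(res$history$best), res$best_energy)
  expect_equal(res$history$best[res$g_c + 1L], res$best_energy)
  if (res$g_c > 0)
    expect_gt(res$history$best[res$g_c], res$best_energy)
})

test_that("guided initialization starts populations at lower energy than random", {
  set.seed(191)
  b <- load_benchmarks("square8")
  mg <- mr <- numeric(0)
  for (i in seq_len(nrow(b))) {
    mg <- c(mg, mean(build_population(b$seq[[i]], size = 100,
                                      method = "guided")$population$energy))
    mr <- c(mr, mean(build_population(b$seq[[i]], size = 100,
                                      method = "random")$population$energy))
  }
  expect_true(all(mg <= mr))
})

test_that("convergence rate follows the closeness formula", {
  expect_equal(convergence_rate(-8, -9), 88.9, tolerance = 1e-3)
  expect_equal(convergence_rate(-5, -9), 55.6, tolerance = 1e-3)
  expect_equal(convergence_rate(-7, -7), 100)
  expect_error(convergence_rate(-5, 0), "non-zero")
})
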
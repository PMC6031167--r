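# Shared test helpers: independent (pure-R) oracles and random generators.

# brute-force H-H contact energy by pair enumeration -- independent of the
# package's grid-based energy path
r_energy <- function(coords, residues, lattice = "square") {
  lat <- lattice_spec(lattice)
  key <- paste(lat$contacts[, 1], lat$contacts[, 2])
  L <- nrow(coords)
  cnt <- 0L
  for (i in seq_len(L - 2)) {
    for (j in (i + 2):L) {
      if (residues[i] == "H" && residues[j] == "H" &&
          paste(coords[j, 1] - coords[i, 1],
                coords[j, 2] - coords[i, 2]) %in% key)
        cnt <- cnt + 1L
    }
  }
  -cnt
}

r_is_saw <- function(coords) !anyDuplicated(paste(coords[, 1], coords[, 2]))

random_hp_string <- function(L, p_h = 0.5) {
  paste(sample(c("H", "P"), L, replace = TRUE, prob = c(p_h, 1 - p_h)),
        collapse = "")
}

# random SAW conformation by rejection sampling over uniform move strings
# (independent of the guided initializer); L must be small
random_saw_conf <- function(seq, lattice = "square", max_tries = 10000) {
  for (t in seq_len(max_tries)) {
    r <- random_conformation(seq, lattice)
    if (r$valid) return(r$conformation)
  }
  stop("no SAW found")
}

tiny_config <- function(...) {
  args <- utils::modifyList(list(population_size = 30L, max_generations = 40L,
                                 stagnation_window = 40L), list(...))
  do.call(search_config, args)
}
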
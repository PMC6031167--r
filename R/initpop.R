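# Tier-1 population construction: naive random initializer (baseline),
# constraint-aware guided initializer (always SAW), validity statistics.

#' Draw one random conformation (baseline initializer)
#'
#' The first two residues are fixed at (0,0) and (1,0); the remaining L-2
#' moves are drawn uniformly over the lattice alphabet. No repair is
#' attempted: the conformation is returned together with its SAW verdict.
#'
#' @param seq an [hp_sequence()].
#' @param lattice lattice name or [lattice_spec()].
#' @return list with `conformation` and `valid`.
#' @export
random_conformation <- function(seq, lattice = "square") {
  seq <- hp_sequence(seq)
  lat <- lattice_spec(lattice)
  L <- seq$length
  if (L < 2) stop("need at least two residues")
  k <- length(lat$moves)
  codes <- c(0L, if (L > 2) sample.int(k, L - 2L, replace = TRUE) - 1L)
  conf <- conformation_from_codes(codes, lat)
  list(conformation = conf, valid = conf$valid)
}

#' Draw one guided conformation (constraint-aware initializer)
#'
#' Grows the chain one residue at a time over an occupancy map of placed
#' coordinates: each step draws a random move, retries among the remaining
#' unoccupied neighbor sites when the target is occupied, and backtracks one
#' residue on a dead end. The result is *always* a self-avoiding walk. When
#' the residue being placed is hydrophobic, with probability `h_bias` the
#' draw prefers free sites already in contact with a placed H residue,
#' seeding a hydrophobic core.
#'
#' @inheritParams random_conformation
#' @param h_bias probability of the hydrophobic-neighbor preference in
#'   \[0, 1\]; 0 disables it.
#' @return an `hp_conformation` (SAW-valid by construction).
#' @export
guided_conformation <- function(seq, lattice = "square", h_bias = 0.5) {
  seq <- hp_sequence(seq)
  lat <- lattice_spec(lattice)
  if (seq$length < 2) stop("need at least two residues")
  codes <- cpp_guided(seq$residues == "H", lat$id, h_bias)
  conformation_from_codes(codes, lat)
}

#' Generate a batch of initial conformations and tally validity
#'
#' Runs one initializer `n` times without redrawing and reports the
#' batch statistics: `n_generated`, valid count `n_valid` (N_v, or N_k for
#' the guided method, for which it always equals `n`), invalid count
#' `n_invalid` (N_i) and the best H-H contact count among the valid draws
#' (`best_hh`).
#'
#' @inheritParams guided_conformation
#' @param n batch size.
#' @param method `"guided"` or `"random"`.
#' @return list of class `hp_init_stats`.
#' @export
init_stats <- function(seq, lattice = "square", n = 100,
                       method = c("guided", "random"), h_bias = 0.5) {
  seq <- hp_sequence(seq)
  lat <- lattice_spec(lattice)
  method <- match.arg(method)
  isH <- seq$residues == "H"
  best <- NA_integer_
  nv <- 0L
  for (i in seq_len(n)) {
    if (method == "guided") {
      codes <- cpp_guided(isH, lat$id, h_bias)
      valid <- TRUE
    } else {
      k <- length(lat$moves)
      codes <- c(0L, if (seq$length > 2)
        sample.int(k, seq$length - 2L, replace = TRUE) - 1L)
      valid <- cpp_decode(codes, lat$id)$valid
    }
    if (valid) {
      nv <- nv + 1L
      e <- cpp_energy_batch(matrix(codes, nrow = 1), isH, lat$id)
      best <- max(best, -e, na.rm = TRUE)
    }
  }
  structure(list(n_generated = n, n_valid = nv, n_invalid = n - nv,
                 best_hh = if (nv) best else NA_integer_, method = method),
            class = "hp_init_stats")
}

new_population <- function(codes, energy, age, lat, L) {
  structure(list(codes = codes, energy = as.integer(energy),
                 age = as.integer(age), lattice = lat$name, L = L,
                 size = nrow(codes)),
            class = "hp_population")
}

#' Build an initial population of valid conformations
#'
#' Always returns exactly `size` SAW-valid individuals. With
#' `method = "random"`, invalid draws are discarded, counted, and redrawn;
#' with `method = "guided"` every draw is valid by construction.
#'
#' @inheritParams init_stats
#' @param size population size.
#' @return list with `population` (an `hp_population`: move-code matrix,
#'   energies, ages) and `stats` (an `hp_init_stats` for the build).
#' @export
build_population <- function(seq, lattice = "square", size = 100,
                             method = c("guided", "random"), h_bias = 0.5) {
  seq <- hp_sequence(seq)
  lat <- lattice_spec(lattice)
  method <- match.arg(method)
  stopifnot(size >= 1)
  isH <- seq$residues == "H"
  L <- seq$length
  n_invalid <- 0L
  if (method == "guided") {
    codes <- matrix(0L, nrow = size, ncol = L - 1L)
    for (i in seq_len(size)) codes[i, ] <- cpp_guided(isH, lat$id, h_bias)
  } else {
    rp <- cpp_random_pop(isH, lat$id, size)
    codes <- rp$pop
    n_invalid <- rp$n_invalid
  }
  energy <- cpp_energy_batch(codes, isH, lat$id)
  stats <- structure(
    list(n_generated = size + n_invalid, n_valid = size,
         n_invalid = n_invalid, best_hh = max(-energy), method = method),
    class = "hp_init_stats")
  list(population = new_population(codes, energy, integer(size), lat, L),
       stats = stats)
}

#' Extract one individual from a population
#'
#' @param pop an `hp_population`.
#' @param i index (1-based).
#' @return list with `conformation`, `fitness` (H-H contacts), `energy`,
#'   `age` and `rank` (0 = best, per the fitness-sorted order, ties sharing
#'   the lowest rank of their fitness value).
#' @export
get_individual <- function(pop, i) {
  stopifnot(i >= 1, i <= pop$size)
  conf <- conformation_from_codes(pop$codes[i, ], pop$lattice)
  rk <- rank(pop$energy, ties.method = "min")[i] - 1L
  list(conformation = conf, fitness = -pop$energy[i],
       energy = pop$energy[i], age = pop$age[i], rank = rk)
}

#' @export
print.hp_population <- function(x, ...) {
  cat("HP population:", x$size, "conformations of", x$L, "residues on",
      x$lattice, "lattice; best energy", min(x$energy),
      ", mean", round(mean(x$energy), 2), "\n")
  invisible(x)
}

#' @export
print.hp_init_stats <- function(x, ...) {
  cat("Initializer (", x$method, "): generated ", x$n_generated,
      ", valid ", x$n_valid, ", invalid ", x$n_invalid,
      ", best H-H ", x$best_hh, "\n", sep = "")
  invisible(x)
}
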
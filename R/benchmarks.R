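# Packaged benchmark fixtures, experiment drivers and run logs.

#' Write a per-generation run log as JSON lines
#'
#' One JSON object per generation with the fields of the search history
#' (generation, best, mean, mode_share, action), suitable for streaming
#' analysis of many runs.
#'
#' @param result an `hp_search_result` from [run_search()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(result, path) {
  h <- result$history
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(h)))
    writeLines(jsonlite::toJSON(as.list(h[i, ]), auto_unbox = TRUE), con)
  invisible(path)
}

bench_file <- function(name)
  system.file("extdata", name, package = "hpfold", mustWork = TRUE)

#' Load packaged benchmark sequences
#'
#' Three fixture sets ship with the package:
#' * `square8`: the eight classical square-lattice HP benchmarks
#'   (prefix run-length notation, lengths 18-36) with their reference
#'   ground-state energies `e_star`;
#' * `tri11`: eleven triangular-lattice benchmarks B1-B11 (caret notation,
#'   lengths 20-100) with the energies reported by prior search methods
#'   (`e_hga` ... `e_ossga`) and by the memetic framework (`e_ma`);
#' * `pdb4`: four protein sequences with their HP translations and reported
#'   energies. These records carry no lattice annotation; choose one
#'   explicitly when folding.
#'
#' Every notation is expanded on load and cross-checked against the recorded
#' length; a mismatch is a hard error, guarding against tokenizer
#' regressions.
#'
#' @param set `"square8"`, `"tri11"` or `"pdb4"`.
#' @return data.frame with one row per benchmark; column `seq` is a list of
#'   [hp_sequence()] objects.
#' @export
load_benchmarks <- function(set = c("square8", "tri11", "pdb4")) {
  set <- match.arg(set)
  file <- switch(set, square8 = "bench_square8.tsv",
                 tri11 = "bench_tri11.tsv", pdb4 = "bench_pdb4.tsv")
  df <- read.delim(bench_file(file), stringsAsFactors = FALSE)
  if (set == "pdb4") {
    seqs <- lapply(df$aa_seq, fasta_to_hp)
    for (i in seq_len(nrow(df))) {
      if (as.character(seqs[[i]]) != df$hp_seq[i])
        stop("fixture ", df$id[i],
             ": HP translation does not match the recorded HP string")
    }
    df$lattice <- NA_character_
  } else {
    dialect <- if (set == "square8") "prefix" else "caret"
    seqs <- lapply(df$notation, parse_hp_notation, dialect = dialect)
    df$lattice <- if (set == "square8") "square" else "tri8"
  }
  for (i in seq_len(nrow(df))) {
    if (seqs[[i]]$length != df$length[i])
      stop("fixture ", df$id[i], ": notation expands to ",
           seqs[[i]]$length, " residues but the record says ", df$length[i])
  }
  df$seq <- I(seqs)
  df$source_set <- set
  df
}

#' Initializer comparison experiment
#'
#' For every square-lattice benchmark, generates `n` conformations with the
#' naive random initializer (no redraws) and `n` with the guided
#' initializer, and tabulates valid/invalid counts and the best H-H contact
#' count of each batch. The guided column is always fully valid.
#'
#' @param n batch size per benchmark and method.
#' @param seed optional seed.
#' @param lattice lattice to initialize on.
#' @param h_bias hydrophobic-core bias of the guided initializer.
#' @return data.frame with columns `id`, `L`, `h_random` (best H-H, random),
#'   `n_valid`, `n_invalid`, `h_guided`, `n_guided`.
#' @export
init_benchmark <- function(n = 100, seed = NULL, lattice = "square",
                           h_bias = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  bench <- load_benchmarks("square8")
  out <- lapply(seq_len(nrow(bench)), function(i) {
    s <- bench$seq[[i]]
    r <- init_stats(s, lattice, n, "random")
    g <- init_stats(s, lattice, n, "guided", h_bias = h_bias)
    data.frame(id = bench$id[i], L = s$length,
               h_random = r$best_hh, n_valid = r$n_valid,
               n_invalid = r$n_invalid,
               h_guided = g$best_hh, n_guided = g$n_valid)
  })
  do.call(rbind, out)
}

#' First-tier search comparison (random vs guided initialization)
#'
#' Runs the search once per square benchmark under each initialization
#' method and reports the achieved energies against the reference optima:
#' energy ratio `e_pct`, hydrophobic fraction and the convergence rate of
#' both runs, plus a final row of column averages. The defaults (population
#' 100, 100 generations) probe the first tier rather than full optimization.
#'
#' @param config base [search_config()]; `init_method` and `seed` are set
#'   per run.
#' @param seed base seed.
#' @return data.frame with one row per benchmark plus an `average` row.
#' @export
first_tier_benchmark <- function(config = search_config(max_generations = 100L),
                                 seed = 1L) {
  bench <- load_benchmarks("square8")
  rows <- lapply(seq_len(nrow(bench)), function(i) {
    s <- bench$seq[[i]]
    cfg <- config
    cfg$lattice <- "square"
    cfg$seed <- seed + 2L * (i - 1L)
    cfg$init_method <- "random"
    e_r <- run_search(s, cfg)$best_energy
    cfg$seed <- cfg$seed + 1L
    cfg$init_method <- "guided"
    e_p <- run_search(s, cfg)$best_energy
    es <- bench$e_star[i]
    data.frame(id = as.character(bench$id[i]), e_star = es,
               e_random = e_r, e_guided = e_p,
               e_random_pct = 100 * e_r / es, e_guided_pct = 100 * e_p / es,
               h_pct = hydrophobic_fraction(s),
               c_random = convergence_rate(e_r, es),
               c_guided = convergence_rate(e_p, es))
  })
  df <- do.call(rbind, rows)
  avg <- data.frame(id = "average", e_star = NA, e_random = NA, e_guided = NA,
                    e_random_pct = mean(df$e_random_pct),
                    e_guided_pct = mean(df$e_guided_pct),
                    h_pct = mean(df$h_pct),
                    c_random = mean(df$c_random),
                    c_guided = mean(df$c_guided))
  rbind(df, avg)
}

#' Reported first-tier reference energies
#'
#' The (E, E*) pairs and convergence percentages reported for the eight
#' square benchmarks in the study the fixtures come from, packaged as plain
#' data for arithmetic cross-checks. `e_r` / `e_p` are the reported energies
#' under random and guided initialization; `c_r` / `c_p` the reported
#' convergence rates; `h_pct` the reported hydrophobic percentage.
#'
#' @return data.frame with columns `id`, `e_star`, `e_r`, `e_p`, `h_pct`,
#'   `c_r`, `c_p`.
#' @export
first_tier_reference <- function() {
  read.delim(bench_file("first_tier_reference.tsv"), stringsAsFactors = FALSE)
}

#' Fold a benchmark set
#'
#' Runs the memetic search with restarts on each record of a benchmark set
#' and reports the best energy found, the generation `g_c` of the best run
#' and the gap to the reference optimum. With `restarts = 0` the report
#' contains the best energy of the initial population only.
#'
#' @param set benchmark set name, see [load_benchmarks()], or a data.frame
#'   from it (possibly subset).
#' @param config base [search_config()].
#' @param restarts restarts per record (each with its own seed).
#' @param seed base seed.
#' @param use_target if `TRUE` (default), each record's reference energy is
#'   used as the early-stop target.
#' @param lattice lattice override; required for `pdb4` records.
#' @return data.frame with columns `id`, `L`, `e_star`, `e_best`, `g_c`,
#'   `n_runs`, `reached`.
#' @export
fold_benchmarks <- function(set = "square8", config = search_config(),
                            restarts = 20L, seed = 1L, use_target = TRUE,
                            lattice = NULL) {
  bench <- if (is.data.frame(set)) set else load_benchmarks(set)
  rows <- lapply(seq_len(nrow(bench)), function(i) {
    s <- bench$seq[[i]]
    cfg <- config
    cfg$lattice <- if (!is.null(lattice)) lattice else bench$lattice[i]
    if (is.na(cfg$lattice))
      stop("record ", bench$id[i], " carries no lattice; pass `lattice`")
    e_star <- if ("e_star" %in% names(bench)) bench$e_star[i] else NA
    target <- if (use_target && !is.na(e_star)) e_star else NULL
    if (restarts == 0L) {
      if (!is.null(cfg$seed)) set.seed(cfg$seed + i)
      pop <- build_population(s, cfg$lattice, cfg$population_size,
                              cfg$init_method, cfg$h_bias)$population
      return(data.frame(id = as.character(bench$id[i]), L = s$length,
                        e_star = e_star, e_best = min(pop$energy),
                        g_c = 0L, n_runs = 0L,
                        reached = !is.na(e_star) && min(pop$energy) <= e_star))
    }
    fr <- fold_sequence(s, cfg, restarts = restarts,
                        seed = seed + 100L * (i - 1L),
                        target_energy = target)
    data.frame(id = as.character(bench$id[i]), L = s$length, e_star = e_star,
               e_best = fr$best_energy, g_c = fr$g_c, n_runs = fr$n_runs,
               reached = !is.na(e_star) && fr$best_energy <= e_star)
  })
  do.call(rbind, rows)
}
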
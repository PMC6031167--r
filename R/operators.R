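# Tier-2 variation operators: sequence-pattern-triggered helix and sheet
# rewrites, corner and pull moves, and the dispatching mutation.

.op_kinds <- c(corner = 0L, pull = 1L, helix_down = 2L, helix_up = 3L,
               sheet = 4L)
.helix_down_pattern <- "PPHPPHPP"  # P2HP2HP2 expanded
.helix_up_pattern <- "HPPHHPPH"    # HP2H2P2H expanded

#' Locate motif sites in an HP sequence
#'
#' Scans the expanded residue string left to right for the three mutation
#' triggers: the downward-helix pattern `PPHPPHPP`, the upward-helix pattern
#' `HPPHHPPH`, and sheet sites (a maximal run of three or more identical
#' residues). Matches are non-overlapping; at equal start the helix patterns
#' take precedence over a sheet run.
#'
#' @param seq an [hp_sequence()].
#' @return data.frame with columns `kind` (`"helix_down"`, `"helix_up"`,
#'   `"sheet"`), `start` (1-based residue index) and `span`.
#' @examples
#' find_motif_sites(hp_sequence("PPHPPHPP"))
#' find_motif_sites(hp_sequence("HHHH"))
#' @export
find_motif_sites <- function(seq) {
  seq <- hp_sequence(seq)
  res <- seq$residues
  s <- paste(res, collapse = "")
  L <- seq$length
  kind <- character(0); start <- integer(0); span <- integer(0)
  i <- 1L
  while (i <= L) {
    taken <- 0L
    if (i + 7L <= L) {
      sub <- substr(s, i, i + 7L)
      if (sub == .helix_down_pattern) {
        kind <- c(kind, "helix_down"); start <- c(start, i); span <- c(span, 8L)
        taken <- 8L
      } else if (sub == .helix_up_pattern) {
        kind <- c(kind, "helix_up"); start <- c(start, i); span <- c(span, 8L)
        taken <- 8L
      }
    }
    if (!taken && i + 2L <= L &&
        res[i] == res[i + 1L] && res[i] == res[i + 2L]) {
      j <- i + 2L
      while (j < L && res[j + 1L] == res[i]) j <- j + 1L
      kind <- c(kind, "sheet"); start <- c(start, i); span <- c(span, j - i + 1L)
      taken <- j - i + 1L
    }
    i <- i + max(taken, 1L)
  }
  data.frame(kind = kind, start = start, span = span,
             stringsAsFactors = FALSE)
}

# motif sites as the 0-based integer matrix the C++ engine consumes
motif_matrix <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0L)
    return(matrix(integer(0), ncol = 3))
  cbind(match(sites$kind, c("helix_down", "helix_up", "sheet")) - 1L,
        sites$start - 1L, sites$span)
}

#' Helix move templates
#'
#' The fixed move cycles (period 4) that a helix mutation writes over a
#' motif site: the tight width-2 serpentine that brings the hydrophobic
#' residues of the trigger pattern into lattice contact. On the square (and
#' tri6) lattice the downward helix cycles D,F,U,F and the upward one
#' U,F,D,F; tri8 substitutes the diagonal steps FD/FU.
#'
#' @param lattice lattice name or [lattice_spec()].
#' @return named list of two character vectors, `down` and `up`.
#' @export
helix_templates <- function(lattice = "square") {
  lat <- lattice_spec(lattice)
  if (lat$name == "tri8")
    list(down = c("FD", "F", "FU", "F"), up = c("FU", "F", "FD", "F"))
  else
    list(down = c("D", "F", "U", "F"), up = c("U", "F", "D", "F"))
}

new_mutation_result <- function(parent, seq, res, op) {
  lat <- lattice_spec(parent$lattice)
  if (res$accepted) {
    off <- conformation_from_codes(res$moves, lat)
    e1 <- res$energy
  } else {
    off <- parent
    e1 <- NA_integer_
  }
  e0 <- conformation_energy(parent, seq)$energy
  structure(list(offspring = off, operator_used = op,
                 accepted = isTRUE(res$accepted),
                 delta_energy = if (res$accepted) e1 - e0 else 0L,
                 energy = if (res$accepted) e1 else e0),
            class = "hp_mutation")
}

#' @export
print.hp_mutation <- function(x, ...) {
  cat("Mutation (", x$operator_used, "): ",
      if (x$accepted) paste0("accepted, delta E = ", x$delta_energy)
      else "rejected (parent returned)", "\n", sep = "")
  invisible(x)
}

check_site <- function(site, seq) {
  if (is.data.frame(site)) site <- as.list(site[1, ])
  if (site$start < 1 || site$start + site$span - 1L > seq$length)
    stop("motif site out of range")
  site
}

#' Apply a helix mutation at a motif site
#'
#' Rewrites the move substring covering the site with the fixed helix
#' template (see [helix_templates()]), leaving the anchored first bond
#' untouched, then re-validates the whole chain. On any clash the parent is
#' returned with `accepted = FALSE`.
#'
#' @param conf parent `hp_conformation` (SAW-valid).
#' @param seq the matching [hp_sequence()].
#' @param site one row of [find_motif_sites()] (kind `helix_down` or
#'   `helix_up`).
#' @return an `hp_mutation`: `offspring`, `operator_used`, `accepted`,
#'   `delta_energy`.
#' @export
apply_helix <- function(conf, seq, site) {
  seq <- hp_sequence(seq)
  site <- check_site(site, seq)
  if (!site$kind %in% c("helix_down", "helix_up"))
    stop("site kind must be helix_down or helix_up")
  lat <- lattice_spec(conf$lattice)
  res <- cpp_try_op(conf$codes, seq$residues == "H", lat$id,
                    .op_kinds[[site$kind]], -1L,
                    site$start - 1L, site$span)
  new_mutation_result(conf, seq, res, site$kind)
}

#' Apply a sheet mutation at a motif site
#'
#' Straightens the move substring over a repeat run: every bond in the site
#' repeats the direction entering the site. Clashes are rejected.
#'
#' @inheritParams apply_helix
#' @param site one row of [find_motif_sites()] with kind `sheet`.
#' @return an `hp_mutation`.
#' @export
apply_sheet <- function(conf, seq, site) {
  seq <- hp_sequence(seq)
  site <- check_site(site, seq)
  if (site$kind != "sheet") stop("site kind must be sheet")
  lat <- lattice_spec(conf$lattice)
  res <- cpp_try_op(conf$codes, seq$residues == "H", lat$id,
                    .op_kinds[["sheet"]], -1L, site$start - 1L, site$span)
  new_mutation_result(conf, seq, res, "sheet")
}

#' Corner move
#'
#' If residues i-1, i, i+1 form a bend and the diagonally opposite lattice
#' site is free, residue i flips across the bend (the two incident bonds
#' swap); collinear triples and occupied targets are rejected.
#'
#' @inheritParams apply_helix
#' @param i residue index, 1 < i < L.
#' @return an `hp_mutation`.
#' @export
corner_move <- function(conf, seq, i) {
  seq <- hp_sequence(seq)
  if (i <= 1 || i >= seq$length) stop("corner index must satisfy 1 < i < L")
  lat <- lattice_spec(conf$lattice)
  res <- cpp_try_op(conf$codes, seq$residues == "H", lat$id,
                    .op_kinds[["corner"]], i - 1L, -1L, 0L)
  new_mutation_result(conf, seq, res, "corner")
}

#' Pull move
#'
#' Relocates residue i to a free site adjacent to residue i+1 and drags the
#' preceding residues along the vacated positions until the chain is
#' reconnected; chain ends relocate to a free neighbor of their single
#' neighbor. Any proposal that breaks the self-avoiding walk, a bond length
#' or the (0,0)-(1,0) anchor is rejected and the parent returned.
#'
#' @inheritParams apply_helix
#' @param i residue index, 1 <= i <= L.
#' @return an `hp_mutation`.
#' @export
pull_move <- function(conf, seq, i) {
  seq <- hp_sequence(seq)
  if (i < 1 || i > seq$length) stop("pull index out of range")
  lat <- lattice_spec(conf$lattice)
  res <- cpp_try_op(conf$codes, seq$residues == "H", lat$id,
                    .op_kinds[["pull"]], i - 1L, -1L, 0L)
  new_mutation_result(conf, seq, res, "pull")
}

#' Mutate a conformation (operator dispatch)
#'
#' Exactly one operator attempt per call. If the sequence has motif sites,
#' with probability `motif_prob` a random site's structural operator (helix
#' or sheet) is applied; otherwise a corner or pull move at a random index.
#' Feasibility (SAW) is enforced by rejection; improvement is not required
#' -- selection handles quality.
#'
#' @inheritParams apply_helix
#' @param motif_prob probability of choosing a motif operator when sites
#'   exist.
#' @param sites precomputed [find_motif_sites()] output (computed from `seq`
#'   when `NULL`).
#' @return an `hp_mutation`.
#' @export
mutate_conformation <- function(conf, seq, motif_prob = 0.2, sites = NULL) {
  seq <- hp_sequence(seq)
  if (is.null(sites)) sites <- find_motif_sites(seq)
  L <- seq$length
  if (nrow(sites) > 0 && runif(1) < motif_prob) {
    s <- sites[sample.int(nrow(sites), 1L), ]
    if (s$kind == "sheet") return(apply_sheet(conf, seq, s))
    return(apply_helix(conf, seq, s))
  }
  if (runif(1) < 0.5 && L >= 3) {
    corner_move(conf, seq, 1L + sample.int(L - 2L, 1L))
  } else {
    pull_move(conf, seq, sample.int(L, 1L))
  }
}
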
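# Lattice geometry, relative move encoding, conformation decoding,
# contact energy, canonicalization and the exhaustive enumeration oracle.

.lattice_ids <- c(square = 0L, tri8 = 1L, tri6 = 2L)

#' Lattice specification
#'
#' Geometry of a 2D folding lattice: the ordered move alphabet, the unit step
#' vector of each move, and the contact neighborhood used for H-H contacts.
#'
#' * `square`: moves F, B, U, D with steps (1,0), (-1,0), (0,1), (0,-1);
#' * `tri8`: the triangular lattice as encoded in this framework -- the four
#'   square moves plus the diagonals FU (1,1), BU (-1,1), BD (-1,-1),
#'   FD (1,-1), all eight also acting as contact directions;
#' * `tri6`: a six-neighbor triangular lattice (square steps plus (1,1) and
#'   (-1,-1)), provided for cross-checking against studies that use the
#'   classical six-coordination triangular lattice.
#'
#' Contacts use the same vector set as the moves on every lattice.
#'
#' @param name `"square"`, `"tri8"` or `"tri6"`, or an existing spec.
#' @return an object of class `hp_lattice` with fields `name`, `moves`,
#'   `steps` (k x 2 integer matrix), `contacts` and internal `id`.
#' @export
lattice_spec <- function(name = c("square", "tri8", "tri6")) {
  if (inherits(name, "hp_lattice")) return(name)
  name <- match.arg(name)
  steps <- switch(name,
    square = rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)),
    tri8 = rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)),
    tri6 = rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(-1, -1)))
  moves <- switch(name,
    square = c("F", "B", "U", "D"),
    tri8 = c("F", "B", "U", "D", "FU", "BU", "BD", "FD"),
    tri6 = c("F", "B", "U", "D", "FU", "BD"))
  storage.mode(steps) <- "integer"
  rownames(steps) <- moves
  colnames(steps) <- c("x", "y")
  structure(list(name = name, moves = moves, steps = steps,
                 contacts = steps, id = .lattice_ids[[name]]),
            class = "hp_lattice")
}

#' @export
print.hp_lattice <- function(x, ...) {
  cat("HP lattice '", x$name, "': moves ",
      paste(x$moves, collapse = " "), "\n", sep = "")
  invisible(x)
}

# split a collapsed move string into move symbols (greedy, 2-char first)
split_moves <- function(moves, lattice) {
  lat <- lattice_spec(lattice)
  if (length(moves) > 1L) return(moves)
  text <- moves
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  two <- lat$moves[nchar(lat$moves) == 2L]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (i < length(chars) && paste0(chars[i], chars[i + 1L]) %in% two) {
      out <- c(out, paste0(chars[i], chars[i + 1L]))
      i <- i + 2L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  out
}

moves_to_codes <- function(moves, lat) {
  codes <- match(moves, lat$moves) - 1L
  if (anyNA(codes))
    stop("unknown move symbol '", moves[which(is.na(codes))[1]],
         "' for lattice '", lat$name, "'")
  codes
}

new_conformation <- function(codes, lat, coords, valid) {
  structure(list(moves = lat$moves[codes + 1L], codes = codes,
                 coords = coords, lattice = lat$name, valid = valid),
            class = "hp_conformation")
}

conformation_from_codes <- function(codes, lattice) {
  lat <- lattice_spec(lattice)
  d <- cpp_decode(as.integer(codes), lat$id)
  colnames(d$coords) <- c("x", "y")
  new_conformation(as.integer(codes), lat, d$coords, d$valid)
}

#' Decode a relative move string into a conformation
#'
#' Builds integer coordinates from a move string, anchoring residue 1 at
#' (0,0) and residue 2 at (1,0) (the first move is always F). Validity under
#' the self-avoiding-walk constraint is *reported*, not enforced, so invalid
#' encodings can be inspected.
#'
#' @param moves move symbols: a character vector, or a single collapsed
#'   string such as `"FDDBUBUUFUFDFDFDDBU"`.
#' @param lattice lattice name or [lattice_spec()].
#' @return an `hp_conformation` with fields `moves`, `coords` (L x 2 integer
#'   matrix), `lattice` and `valid`.
#' @examples
#' conf <- decode_conformation("FDDBUBUUFUFDFDFDDBU")
#' conf$valid
#' @export
decode_conformation <- function(moves, lattice = "square") {
  lat <- lattice_spec(lattice)
  sym <- split_moves(moves, lat)
  if (sym[1] != "F")
    stop("the first move is fixed to F (residues 1-2 anchor at (0,0),(1,0))")
  conformation_from_codes(moves_to_codes(sym, lat), lat)
}

#' Re-encode coordinates as a move string
#'
#' @param coords L x 2 integer matrix of lattice positions.
#' @param lattice lattice name or [lattice_spec()].
#' @return character vector of L-1 move symbols.
#' @export
encode_conformation <- function(coords, lattice = "square") {
  lat <- lattice_spec(lattice)
  d <- diff(coords)
  key <- paste(lat$steps[, 1], lat$steps[, 2])
  codes <- match(paste(d[, 1], d[, 2]), key)
  if (anyNA(codes)) {
    p <- which(is.na(codes))[1]
    stop("bond ", p, " -> ", p + 1, " is not a unit lattice step")
  }
  lat$moves[codes]
}

#' @export
print.hp_conformation <- function(x, ...) {
  cat("HP conformation on", x$lattice, "lattice:",
      length(x$moves) + 1L, "residues,",
      if (x$valid) "SAW-valid" else "NOT self-avoiding", "\n")
  cat(" ", paste(x$moves, collapse = ""), "\n")
  invisible(x)
}

#' H-H contact set and free energy of a conformation
#'
#' Enumerates all residue pairs (i, j) with j > i + 1 whose lattice positions
#' differ by a contact vector and whose residues are both hydrophobic. The
#' free energy is minus the number of such pairs; fitness is the H-H contact
#' count itself.
#'
#' @param conf an `hp_conformation` (must be SAW-valid).
#' @param seq an [hp_sequence()] of matching length.
#' @return an `hp_contacts` object: `pairs` (n x 2, 1-based residue indices),
#'   `energy` (non-positive integer), `fitness` (= -energy).
#' @export
conformation_energy <- function(conf, seq) {
  seq <- hp_sequence(seq)
  L <- nrow(conf$coords)
  if (L != seq$length)
    stop("conformation has ", L, " residues but sequence has ", seq$length)
  if (!conf$valid)
    stop("conformation is not a self-avoiding walk")
  lat <- lattice_spec(conf$lattice)
  res <- cpp_contacts(conf$coords, seq$residues == "H", lat$id)
  structure(list(pairs = res$pairs, energy = res$energy,
                 fitness = -res$energy),
            class = "hp_contacts")
}

#' @export
print.hp_contacts <- function(x, ...) {
  cat("H-H contacts:", x$fitness, "(energy", x$energy, ")\n")
  invisible(x)
}

# symmetry group of a lattice: signed-permutation matrices that permute the
# step set
lattice_symmetries <- function(lat) {
  lat <- lattice_spec(lat)
  mats <- list()
  key <- sort(paste(lat$steps[, 1], lat$steps[, 2]))
  for (perm in list(diag(2), rbind(c(0, 1), c(1, 0)))) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      M <- perm * rbind(c(s1, s1), c(s2, s2))
      img <- lat$steps %*% t(M)
      if (identical(sort(paste(img[, 1], img[, 2])), key))
        mats[[length(mats) + 1L]] <- M
    }
  }
  mats
}

#' Canonical (nonisomorphic) encoding of a conformation
#'
#' Maps a conformation to the unique representative of its symmetry class:
#' among all lattice-symmetry images whose first bond is F, the one whose
#' first vertical deviation points up (ties broken by lexicographically
#' smallest move string). All rotations/reflections of one structure share
#' this canonical encoding, so the genotype space is free of isomorphic
#' duplicates.
#'
#' @param conf an `hp_conformation`.
#' @return an `hp_conformation` in canonical form.
#' @export
canonical_conformation <- function(conf) {
  lat <- lattice_spec(conf$lattice)
  mats <- lattice_symmetries(lat)
  xy0 <- sweep(conf$coords, 2, conf$coords[1, ])
  best <- NULL
  for (M in mats) {
    xy <- xy0 %*% t(M)
    if (xy[2, 1] != 1L || xy[2, 2] != 0L) next
    dy <- diff(xy[, 2])
    firstv <- dy[dy != 0][1]
    if (!is.na(firstv) && firstv < 0) next
    mv <- encode_conformation(xy, lat)
    codes <- moves_to_codes(mv, lat)
    if (is.null(best) ||
        isTRUE(paste(codes, collapse = ",") < paste(best, collapse = ","))) {
      best <- codes
    }
  }
  if (is.null(best))
    stop("no symmetry image restores the (0,0)-(1,0) anchor")
  conformation_from_codes(best, lat)
}

#' Exhaustive ground-state search (oracle)
#'
#' Depth-first enumeration of every self-avoiding conformation under the
#' nonisomorphic encoding (first move F; the first vertical deviation is
#' canonicalized upward to remove the reflection). Exact but exponential:
#' intended as an oracle for short chains.
#'
#' @param seq an [hp_sequence()].
#' @param lattice lattice name or [lattice_spec()].
#' @param max_length_guard refuse sequences longer than this (default 16 on
#'   the square lattice, 12 on the triangular lattices).
#' @return list with `best_energy` (exact minimum) and `n_optimal` (number of
#'   optimal canonical conformations).
#' @examples
#' exhaustive_optimum(hp_sequence("HPPH"))$best_energy # -1
#' @export
exhaustive_optimum <- function(seq, lattice = "square", max_length_guard = NULL) {
  seq <- hp_sequence(seq)
  lat <- lattice_spec(lattice)
  if (is.null(max_length_guard))
    max_length_guard <- if (lat$name == "square") 16L else 12L
  if (seq$length > max_length_guard)
    stop("sequence length ", seq$length, " exceeds max_length_guard (",
         max_length_guard, "); exhaustive enumeration would be intractable")
  cpp_exhaustive(seq$residues == "H", lat$id)
}

#' Write / read a conformation as TSV
#'
#' The format is plain text: comment header lines carrying the lattice, the
#' move string and the energy, followed by tab-separated columns
#' `index`, `residue`, `x`, `y`.
#'
#' @param conf an `hp_conformation`.
#' @param seq the matching [hp_sequence()].
#' @param path output file.
#' @return `path`, invisibly (`write_conformation_tsv`); an
#'   `hp_conformation` plus the sequence, for `read_conformation_tsv`.
#' @export
write_conformation_tsv <- function(conf, seq, path) {
  seq <- hp_sequence(seq)
  en <- conformation_energy(conf, seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# lattice: ", conf$lattice),
               paste0("# moves: ", paste(conf$moves, collapse = " ")),
               paste0("# energy: ", en$energy)), con)
  df <- data.frame(index = seq_len(seq$length), residue = seq$residues,
                   x = conf$coords[, 1], y = conf$coords[, 2])
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conformation_tsv
#' @export
read_conformation_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  lattice <- sub("^# lattice:\\s*", "", grep("^# lattice:", hdr, value = TRUE))
  moves <- strsplit(sub("^# moves:\\s*", "",
                        grep("^# moves:", hdr, value = TRUE)), "\\s+")[[1]]
  df <- read.delim(textConnection(lines[!grepl("^#", lines)]))
  conf <- decode_conformation(moves, lattice)
  if (!all(conf$coords[, 1] == df$x & conf$coords[, 2] == df$y))
    stop("coordinates in ", path, " do not match the move string")
  list(conformation = conf,
       seq = new_hp_seq(as.character(df$residue)))
}
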
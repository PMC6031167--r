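# HP sequences: run-length notation parsing, amino-acid translation,
# sequence statistics.

#' HP sequence object
#'
#' An `hp_seq` holds an ordered string of residues over the two-letter
#' hydrophobic/polar alphabet, together with the notation it was parsed from.
#' Construct one with [hp_sequence()], [parse_hp_notation()], or
#' [fasta_to_hp()].
#'
#' @param residues character vector of "H"/"P" symbols.
#' @param source_notation the original text the sequence was derived from.
#' @return an object of class `hp_seq` with fields `residues`, `length`,
#'   `n_h` (hydrophobic count) and `source_notation`.
#' @keywords internal
new_hp_seq <- function(residues, source_notation = paste(residues, collapse = "")) {
  stopifnot(length(residues) >= 1L, all(residues %in% c("H", "P")))
  structure(
    list(residues = residues,
         length = length(residues),
         n_h = sum(residues == "H"),
         source_notation = source_notation),
    class = "hp_seq")
}

#' Create an HP sequence
#'
#' Accepts a plain HP string, either run-length notation dialect, or an
#' existing `hp_seq` (returned unchanged).
#'
#' @param x character scalar (plain HP string or run-length notation) or an
#'   `hp_seq`.
#' @param notation one of `"auto"`, `"prefix"`, `"caret"`, `"plain"`. With
#'   `"auto"`, a `^` selects the caret dialect, any digit the prefix dialect,
#'   otherwise the string is taken verbatim.
#' @return an `hp_seq`.
#' @examples
#' hp_sequence("2H5P2H3PH3PHP")        # prefix run-length, expands to 18-mer
#' hp_sequence("P^2HP^2(H^2P^4)^3H^2") # caret run-length
#' hp_sequence("HPHP")
#' @export
hp_sequence <- function(x, notation = c("auto", "prefix", "caret", "plain")) {
  if (inherits(x, "hp_seq")) return(x)
  notation <- match.arg(notation)
  if (notation == "auto" && !grepl("[0-9^()]", x)) notation <- "plain"
  if (notation == "plain") {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% c("H", "P"))
    if (length(bad))
      stop("invalid residue symbol at position ", bad[1], ": '", chars[bad[1]], "'")
    return(new_hp_seq(chars, x))
  }
  parse_hp_notation(x, dialect = notation)
}

#' Parse run-length HP notation
#'
#' Two dialects are understood. In the *prefix* dialect a (multi-digit)
#' number multiplies the immediately following symbol or parenthesized
#' group: `"2H"` is `HH`, `"3(2H4P)"` is `HHPPPP` repeated three times. In
#' the *caret* dialect a trailing `^n` repeats the preceding symbol or
#' group: `"H^2"` is `HH`, `"(HP)^2"` is `HPHP`. Groups nest in both
#' dialects. `"auto"` selects caret when a `^` is present, prefix otherwise.
#'
#' @param text run-length HP string over `H P 0-9 ( ) ^`.
#' @param dialect `"auto"`, `"prefix"` or `"caret"`.
#' @return an [hp_sequence()] object; `$length` equals the expansion length.
#' @examples
#' parse_hp_notation("2H5P2H3PH3PHP")$length        # 18
#' parse_hp_notation("H^12(PH)^2", "caret")$length  # 16
#' @export
parse_hp_notation <- function(text, dialect = c("auto", "prefix", "caret")) {
  dialect <- match.arg(dialect)
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("'text' must be a non-empty character scalar")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  ok <- chars %in% c("H", "P", "(", ")", "^", as.character(0:9))
  if (any(!ok)) {
    p <- which(!ok)[1]
    stop("character outside the HP notation alphabet at position ", p,
         ": '", chars[p], "'")
  }
  if (dialect == "auto")
    dialect <- if (any(chars == "^")) "caret" else "prefix"
  if (dialect == "prefix" && any(chars == "^"))
    stop("'^' found at position ", which(chars == "^")[1],
         " but dialect is 'prefix'")

  n <- length(chars)
  pos <- 1L
  peek <- function() if (pos <= n) chars[pos] else NA_character_
  read_number <- function() {
    start <- pos
    while (pos <= n && chars[pos] %in% as.character(0:9)) pos <<- pos + 1L
    as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
  }
  # returns expanded character vector; stops at ')' or end of input
  parse_seq <- function() {
    out <- character(0)
    repeat {
      c0 <- peek()
      if (is.na(c0) || c0 == ")") return(out)
      if (dialect == "prefix") {
        mult <- 1L
        if (c0 %in% as.character(0:9)) {
          at <- pos
          mult <- read_number()
          c0 <- peek()
          if (is.na(c0) || !(c0 %in% c("H", "P", "(")))
            stop("dangling multiplier at position ", at)
        }
        unit <- parse_unit()
        out <- c(out, rep(unit, mult))
      } else {
        if (c0 %in% as.character(0:9))
          stop("bare number at position ", pos,
               " (caret dialect puts repeats after '^')")
        unit <- parse_unit()
        if (identical(peek(), "^")) {
          pos <<- pos + 1L
          if (is.na(peek()) || !(peek() %in% as.character(0:9)))
            stop("dangling '^' at position ", pos - 1L)
          unit <- rep(unit, read_number())
        }
        out <- c(out, unit)
      }
    }
  }
  parse_unit <- function() {
    c0 <- peek()
    if (c0 %in% c("H", "P")) { pos <<- pos + 1L; return(c0) }
    if (c0 == "(") {
      at <- pos
      pos <<- pos + 1L
      inner <- parse_seq()
      if (!identical(peek(), ")"))
        stop("unbalanced '(' at position ", at)
      pos <<- pos + 1L
      if (dialect == "caret" && identical(peek(), "^")) {
        pos <<- pos + 1L
        if (is.na(peek()) || !(peek() %in% as.character(0:9)))
          stop("dangling '^' at position ", pos - 1L)
        inner <- rep(inner, read_number())
      }
      return(inner)
    }
    stop("unexpected '", c0, "' at position ", pos)
  }

  res <- parse_seq()
  if (pos <= n)
    stop("unbalanced ')' at position ", pos)
  if (!length(res)) stop("notation expands to an empty sequence")
  new_hp_seq(res, text)
}

#' Compress an HP sequence to run-length notation
#'
#' Greedy run-length encoding: maximal runs of one symbol become a multiplier
#' (prefix dialect) or exponent (caret dialect). Re-parsing the result yields
#' the identical residue string.
#'
#' @param seq an [hp_sequence()].
#' @param dialect `"prefix"` or `"caret"`.
#' @return character scalar.
#' @export
hp_compress <- function(seq, dialect = c("prefix", "caret")) {
  seq <- hp_sequence(seq)
  dialect <- match.arg(dialect)
  r <- rle(seq$residues)
  parts <- if (dialect == "prefix") {
    ifelse(r$lengths > 1L, paste0(r$lengths, r$values), r$values)
  } else {
    ifelse(r$lengths > 1L, paste0(r$values, "^", r$lengths), r$values)
  }
  paste(parts, collapse = "")
}

#' Hydrophobic / polar residue classes
#'
#' The residue partition used for amino-acid to HP translation. Note that
#' proline is in the hydrophobic class and histidine in the polar class;
#' this partition is deliberately frozen, but a modified copy can be passed
#' to [fasta_to_hp()].
#'
#' @return named list with components `H` and `P`, each a character vector of
#'   one-letter amino-acid codes.
#' @export
hp_residue_classes <- function() {
  list(H = c("A", "G", "I", "L", "M", "F", "P", "W", "V"),
       P = c("R", "N", "D", "C", "E", "Q", "H", "K", "S", "T", "Y"))
}

#' Translate an amino-acid sequence to an HP sequence
#'
#' @param amino_seq one-letter amino-acid string (or character vector of
#'   single letters) over the 20 standard codes.
#' @param classes residue partition, defaulting to [hp_residue_classes()].
#' @return an [hp_sequence()] of the same length.
#' @examples
#' as.character(fasta_to_hp("GVIDT")) # "HHHPP"
#' @export
fasta_to_hp <- function(amino_seq, classes = hp_residue_classes()) {
  chars <- if (length(amino_seq) == 1L)
    strsplit(toupper(amino_seq), "", fixed = TRUE)[[1]] else toupper(amino_seq)
  known <- c(classes$H, classes$P)
  bad <- which(!chars %in% known)
  if (length(bad))
    stop("unsupported residue code(s) ",
         paste(unique(chars[bad]), collapse = ", "),
         " at position(s) ", paste(bad, collapse = ", "))
  res <- ifelse(chars %in% classes$H, "H", "P")
  new_hp_seq(res, paste(chars, collapse = ""))
}

#' Read a FASTA file and translate the record to an HP sequence
#'
#' @param path FASTA file with one or more protein records.
#' @param id optional record name; the first record is used when `NULL`.
#' @param classes residue partition, see [fasta_to_hp()].
#' @return an [hp_sequence()].
#' @export
read_hp_fasta <- function(path, id = NULL, classes = hp_residue_classes()) {
  recs <- Biostrings::readBStringSet(path)
  if (!length(recs)) stop("no records in ", path)
  if (!is.null(id)) {
    hit <- which(sub("\\s.*$", "", names(recs)) == id)
    if (!length(hit)) stop("no record named '", id, "' in ", path)
    recs <- recs[hit[1]]
  }
  fasta_to_hp(as.character(recs[[1]]), classes = classes)
}

#' Hydrophobic fraction of a sequence
#'
#' @param seq an [hp_sequence()] (or anything coercible to one).
#' @return percentage `100 * n_h / L`.
#' @examples
#' hydrophobic_fraction(hp_sequence("2H5P2H3PH3PHP")) # 33.3...
#' @export
hydrophobic_fraction <- function(seq) {
  seq <- hp_sequence(seq)
  100 * seq$n_h / seq$length
}

#' @export
as.character.hp_seq <- function(x, ...) paste(x$residues, collapse = "")

#' @export
length.hp_seq <- function(x) x$length

#' @export
print.hp_seq <- function(x, ...) {
  cat("HP sequence: L =", x$length, ", n_H =", x$n_h,
      sprintf("(H%% = %.1f)\n", 100 * x$n_h / x$length))
  cat(" ", as.character(x), "\n")
  if (!identical(x$source_notation, as.character(x)))
    cat("  from:", x$source_notation, "\n")
  invisible(x)
}
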
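# Degenerate fixed-width motif model: parsing/printing the bracket dialect,
# exact set matching over sequences, presence profiles, PWMs.
#
# Matching semantics: fixed-width allowed-set matching only (no regex
# quantifiers or backtracking); the wildcard '.' is the full 20-residue
# canonical alphabet, so non-canonical codes (X, U, B, Z, *) match nothing.

#' Construct a motif from a list of allowed residue sets
#'
#' @param sets List of character vectors, each a non-empty subset of
#'   [aa_alphabet()]. Width must be at least 2 and terminal positions may not
#'   be full wildcards (a terminal wildcard changes no carrier set, only
#'   instance offsets).
#' @return A `slim_motif`.
#' @export
#' @examples
#' motif(list("S", "P", aa_alphabet(), c("R", "K")))
motif <- function(sets) {
  if (length(sets) < 2) stop("motif width must be >= 2")
  sets <- lapply(sets, function(s) {
    s <- sort(unique(toupper(as.character(s))))
    if (length(s) == 0) stop("empty allowed-set")
    bad <- setdiff(s, AA_CANON)
    if (length(bad))
      stop("non-canonical residue(s) in allowed-set: ",
           paste(bad, collapse = ", "))
    s
  })
  w <- length(sets)
  if (length(sets[[1]]) == 20 || length(sets[[w]]) == 20)
    stop("terminal positions may not be wildcards")
  structure(list(sets = sets, width = w), class = "slim_motif")
}

is_wildcard_pos <- function(m) vapply(m$sets, length, 1L) == 20L

#' Parse a motif pattern string
#'
#' The dialect is single residue letters, `.` for any canonical residue, and
#' `[XYZ]` for an explicit set, e.g. `"SP.[RK]"`. Parse errors report the
#' 1-based column.
#'
#' @param pattern Pattern string.
#' @return A `slim_motif`; `parse_motif(format(m))` reproduces `m`.
#' @export
#' @examples
#' parse_motif("SP.[RK]")
parse_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == ".") {
      sets <- c(sets, list(AA_CANON))
      i <- i + 1L
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (length(close) == 0)
        stop("unbalanced bracket at column ", i, " in '", pattern, "'")
      close <- close[1]
      inner <- chars[seq.int(i + 1L, length.out = close - i - 1L)]
      if (length(inner) == 0)
        stop("empty bracket set at column ", i, " in '", pattern, "'")
      bad <- which(!(inner %in% AA_CANON))
      if (length(bad))
        stop("unknown character '", inner[bad[1]], "' at column ",
             i + bad[1], " in '", pattern, "'")
      sets <- c(sets, list(inner))
      i <- close + 1L
    } else if (ch %in% AA_CANON) {
      sets <- c(sets, list(ch))
      i <- i + 1L
    } else {
      stop("unknown character '", ch, "' at column ", i, " in '", pattern, "'")
    }
  }
  motif(sets)
}

#' @export
format.slim_motif <- function(x, ...) {
  paste(vapply(x$sets, function(s) {
    if (length(s) == 20) "."
    else if (length(s) == 1) s
    else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @export
print.slim_motif <- function(x, ...) {
  cat("<slim_motif> ", format(x), " (width ", x$width,
      ", degeneracy ", motif_degeneracy(x), ")\n", sep = "")
  invisible(x)
}

#' Number of exact words matching a motif
#'
#' The product over positions of allowed-set sizes.
#'
#' @param m A `slim_motif`.
#' @return Integer-valued numeric.
#' @export
#' @examples
#' motif_degeneracy(parse_motif("SP.[RK]")) # 40
motif_degeneracy <- function(m) prod(vapply(m$sets, length, 1L))

# regex over explicit character classes; the wildcard expands to the
# canonical alphabet so X/U/B/Z/* never match
motif_regex <- function(m) {
  paste0(vapply(m$sets, function(s)
    paste0("[", paste(s, collapse = ""), "]"), character(1)), collapse = "")
}

#' Find all (overlapping) motif matches in one sequence
#'
#' @param sequence Amino-acid string.
#' @param m A `slim_motif` or pattern string.
#' @return Integer vector of 0-based start offsets, ascending; empty when the
#'   sequence is shorter than the motif.
#' @export
#' @examples
#' scan_sequence("MSPARQSPIK", "SP.[RK]") # 1, 6
scan_sequence <- function(sequence, m) {
  if (is.character(m)) m <- parse_motif(m)
  scan_many(sequence, m)[[1]]
}

# vectorized overlapping scan via zero-width lookahead
scan_many <- function(sequences, m) {
  rx <- paste0("(?=", motif_regex(m), ")")
  res <- gregexpr(rx, sequences, perl = TRUE)
  lapply(res, function(r) {
    s <- as.integer(r)
    if (length(s) == 1 && s[1] == -1L) integer(0) else s - 1L
  })
}

present_many <- function(sequences, m) {
  grepl(motif_regex(m), sequences, perl = TRUE)
}

#' Build the presence/instance profile of a motif over a proteome
#'
#' The motif profile is the binary presence/absence of at least one exact
#' match per protein, in the given id order, together with all (overlapping)
#' instance start offsets.
#'
#' @param prot A [proteome()].
#' @param m A `slim_motif` or pattern string.
#' @param ids Ordered protein ids defining profile rows (default: all
#'   proteome entries in stored order).
#' @return A `slim_profile`: list with `motif`, `ids`, `present` (logical),
#'   `instances` (list of 0-based starts).
#' @export
build_profile <- function(prot, m, ids = names(prot)) {
  if (is.character(m)) m <- parse_motif(m)
  unknown <- setdiff(ids, names(prot))
  if (length(unknown))
    stop("unknown protein id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  seqs <- unclass(prot)[ids]
  inst <- scan_many(seqs, m)
  structure(list(motif = m, ids = ids,
                 present = lengths(inst) > 0L, instances = inst),
            class = "slim_profile")
}

#' @export
print.slim_profile <- function(x, ...) {
  cat("<slim_profile> ", format(x$motif), ": ", sum(x$present), "/",
      length(x$ids), " carriers, ", sum(lengths(x$instances)),
      " instances\n", sep = "")
  invisible(x)
}

#' Position-weight matrix over all motif instances
#'
#' Row `j` gives the frequency of each canonical residue at motif offset
#' `j - 1` over every instance (overlapping instances all counted). Rows sum
#' to 1. Columns are the 20 canonical residues in alphabetical order.
#'
#' @param profile A `slim_profile` with at least one instance.
#' @param prot The [proteome()] the profile was built on.
#' @return Numeric matrix, width x 20.
#' @export
pwm_from_instances <- function(profile, prot) {
  w <- profile$motif$width
  n_i <- lengths(profile$instances)
  if (sum(n_i) == 0) stop("no motif instances; PWM undefined")
  seqs <- unclass(prot)[profile$ids]
  starts <- unlist(profile$instances, use.names = FALSE)
  words <- substring(rep(seqs, n_i), starts + 1L, starts + w)
  mat <- matrix(0, nrow = w, ncol = 20,
                dimnames = list(NULL, AA_CANON))
  for (j in seq_len(w)) {
    cnt <- table(factor(substring(words, j, j), levels = AA_CANON))
    mat[j, ] <- as.numeric(cnt)
  }
  mat / rowSums(mat)
}
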
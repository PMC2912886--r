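#' Degenerate protein consensus patterns
#'
#' A consensus pattern is an ordered list of allowed amino-acid sets, one
#' per position (a set containing all 20 residues is a wildcard).  Two
#' patterns of interest ship with the package:
#'
#' * [sumo_pattern()] — the SUMOylation acceptor consensus Psi-K-x-E,
#'   where Psi is an aliphatic residue (I, L, V) and x any residue.
#' * [phi_c_x_i_pattern()] — Phi-C-x-I with Phi taken verbatim as
#'   (K, L, Y); the K in this "hydrophobic" class is chemically odd but
#'   is reproduced as reported, and the class is configurable.
#'
#' @param name pattern name.
#' @param positions list of character vectors of allowed residues.
#' @return an object of class `consensus_pattern`.
#' @export
consensus_pattern <- function(name, positions) {
  if (length(positions) < 2L) stop("pattern must have length >= 2")
  positions <- lapply(positions, function(p) {
    p <- toupper(as.character(p))
    if (!length(p)) stop("empty position set")
    bad <- setdiff(p, strsplit(AA_ALPHABET, "")[[1L]])
    if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
    p
  })
  structure(list(name = name, positions = positions),
            class = "consensus_pattern")
}

#' @rdname consensus_pattern
#' @export
sumo_pattern <- function() {
  consensus_pattern("psi-k-x-e",
                    list(c("I", "L", "V"), "K",
                         strsplit(AA_ALPHABET, "")[[1L]], "E"))
}

#' @rdname consensus_pattern
#' @param phi residue class for the first position.
#' @export
phi_c_x_i_pattern <- function(phi = c("K", "L", "Y")) {
  consensus_pattern("phi-c-x-i",
                    list(phi, "C", strsplit(AA_ALPHABET, "")[[1L]], "I"))
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat(sprintf("consensus_pattern '%s': %s\n", x$name,
              paste(vapply(x$positions, function(p)
                if (length(p) == 20L) "." else
                  if (length(p) == 1L) p else
                    paste0("[", paste(p, collapse = ""), "]"),
                character(1)), collapse = "")))
  invisible(x)
}

#' Scan a protein sequence for a consensus pattern
#'
#' Reports every (possibly overlapping) window whose residues all lie in
#' their position's allowed set.  Case-insensitive; coordinates 0-based.
#'
#' @param seq protein sequence string.
#' @param pattern a [consensus_pattern()].
#' @return data frame with `start` (0-based) and `match` (the matched
#'   substring), sorted by start.
#' @export
scan_consensus <- function(seq, pattern) {
  stopifnot(inherits(pattern, "consensus_pattern"))
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% strsplit(AA_ALPHABET, "")[[1L]])
  if (length(bad))
    stop(sprintf("illegal residue '%s' at position %d", chars[bad[1L]], bad[1L]))
  w <- length(pattern$positions)
  n <- length(chars)
  if (n < w)
    return(data.frame(start = integer(0), match = character(0),
                      stringsAsFactors = FALSE))
  ok <- rep(TRUE, n - w + 1L)
  for (i in seq_len(w)) {
    ok <- ok & chars[i:(n - w + i)] %in% pattern$positions[[i]]
  }
  starts <- which(ok) - 1L
  data.frame(start = starts,
             match = if (length(starts)) substring(seq, starts + 1L, starts + w)
                     else character(0),
             stringsAsFactors = FALSE)
}

#' Count consensus matches per protein
#'
#' @param proteins a protein [sequence_set()].
#' @param pattern a [consensus_pattern()]; default [sumo_pattern()].
#' @return data frame with one row per protein: `id`, `count`, `present`.
#' @export
count_sumo_sites <- function(proteins, pattern = sumo_pattern()) {
  stopifnot(inherits(proteins, "sequence_set"))
  counts <- vapply(names(proteins), function(id)
    nrow(scan_consensus(proteins[[id]], pattern)), integer(1))
  data.frame(id = names(proteins), count = unname(counts),
             present = unname(counts) > 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}
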
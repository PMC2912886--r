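#' Sequence sets
#'
#' A `sequence_set` is an ordered collection of named sequences, either DNA
#' (alphabet `A`, `C`, `G`, `T`) or protein (the 20 standard amino acids).
#' Identifiers must be unique and non-empty, sequences non-empty, and the
#' alphabet consistent within a set.
#'
#' @param ids character vector of unique, non-empty record identifiers.
#' @param sequences character vector of sequences (same length as `ids`).
#' @param alphabet `"dna"`, `"protein"` or `"auto"` (detect: a set whose
#'   residues are all in `ACGT` is DNA, otherwise protein).
#' @return An object of class `sequence_set`: a named character vector with
#'   an `alphabet` attribute.
#' @export
sequence_set <- function(ids, sequences, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences))
    stop("ids and sequences must have the same length")
  if (any(!nzchar(ids)))
    stop("sequence ids must be non-empty")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(sequences)))
    stop("empty sequence for id(s): ", paste(ids[!nzchar(sequences)], collapse = ", "))
  if (alphabet == "auto") {
    alphabet <- if (all(!grepl("[^ACGT]", sequences))) "dna" else "protein"
  }
  allowed <- if (alphabet == "dna") "ACGT" else AA_ALPHABET
  bad <- regexpr(sprintf("[^%s]", allowed), sequences)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                 substr(sequences[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  structure(stats::setNames(sequences, ids), class = "sequence_set",
            alphabet = alphabet)
}

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"

#' @export
`[.sequence_set` <- function(x, i) {
  structure(NextMethod(), class = "sequence_set", alphabet = attr(x, "alphabet"))
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d %s record(s)\n", length(x), attr(x, "alphabet")))
  show <- utils::head(names(x), 6L)
  for (id in show)
    cat(sprintf("  %s (%d)\n", id, nchar(x[[id]])))
  if (length(x) > 6L) cat(sprintf("  ... and %d more\n", length(x) - 6L))
  invisible(x)
}

#' Read and write FASTA files
#'
#' `read_fasta()` reads a (DNA or protein) FASTA file into a
#' [sequence_set()], preserving record order and upper-casing sequences.
#' Parsing is delegated to [Biostrings::readBStringSet()]; validation
#' (unique non-empty ids, non-empty sequences, legal alphabet) is strict
#' and fails loudly.
#'
#' @param path path to a FASTA file.
#' @param alphabet passed to [sequence_set()].
#' @return `read_fasta()`: a `sequence_set`.
#' @export
read_fasta <- function(path, alphabet = "auto") {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", names(ss))
  sequence_set(ids, as.character(ss), alphabet = alphabet)
}

#' @rdname read_fasta
#' @param x a `sequence_set`.
#' @param width line-wrap width for sequence lines.
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "sequence_set"))
  lines <- unlist(lapply(names(x), function(id) {
    s <- x[[id]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' AP-axis profile sets
#'
#' A `profile_set` holds one or more value tracks (TF protein concentration
#' or CRM expression) sampled at a common, strictly increasing set of
#' anterior-posterior (AP) positions, in percent egg length.
#'
#' @param axis numeric vector of AP positions, strictly increasing.
#' @param profiles named list (or matrix with rownames) of numeric vectors,
#'   each the same length as `axis`.
#' @return An object of class `profile_set`: a list with elements `axis`
#'   and `profiles` (a tracks-by-positions numeric matrix).
#' @export
profile_set <- function(axis, profiles) {
  axis <- as.numeric(axis)
  if (length(axis) < 1L || any(!is.finite(axis)))
    stop("axis must be finite and non-empty")
  if (any(diff(axis) <= 0))
    stop("axis positions must be strictly increasing")
  if (is.list(profiles)) {
    if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
      stop("profiles must be named")
    mat <- do.call(rbind, lapply(profiles, as.numeric))
    rownames(mat) <- names(profiles)
  } else {
    mat <- as.matrix(profiles)
  }
  if (ncol(mat) != length(axis))
    stop(sprintf("profile length (%d) does not match axis length (%d)",
                 ncol(mat), length(axis)))
  if (anyNA(mat) || any(!is.finite(mat)))
    stop("profiles must be finite and non-missing")
  structure(list(axis = axis, profiles = mat), class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("profile_set: %d track(s) x %d AP position(s) [%g, %g]\n",
              nrow(x$profiles), length(x$axis), min(x$axis), max(x$axis)))
  invisible(x)
}

#' Read and write tab-separated profile tables
#'
#' The on-disk convention is a TSV whose first header cell is `id` and
#' whose remaining header cells are the AP positions; each subsequent row
#' is a track id followed by one numeric value per position.  Lines
#' starting with `#` are treated as comments.
#'
#' @param path path to a TSV file.
#' @return `read_profile_table()`: a [profile_set()].
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 2L) stop("profile table needs a header and at least one row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (header[1L] != "id")
    stop("profile table header must start with 'id', got '", header[1L], "'")
  npos <- length(header) - 1L
  axis <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(axis)) stop("non-numeric AP position in header")
  rows <- cells[-1L]
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != npos + 1L)
      stop(sprintf("ragged row %d: expected %d fields, got %d",
                   i + 1L, npos + 1L, length(rows[[i]])))
  }
  ids <- vapply(rows, `[[`, character(1), 1L)
  vals <- lapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at row %d, column %d ('%s')",
                   i + 1L, j + 1L, rows[[i]][j + 1L]))
    }
    v
  })
  profile_set(axis, stats::setNames(vals, ids))
}

#' @rdname read_profile_table
#' @param x a `profile_set`.
#' @param comment optional character vector of comment lines (written with
#'   a leading `#`).
#' @return `write_profile_table()`: `path`, invisibly.
#' @export
write_profile_table <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "profile_set"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("id", format_num(x$axis)), collapse = "\t"), con)
  for (id in rownames(x$profiles))
    writeLines(paste(c(id, format_num(x$profiles[id, ])), collapse = "\t"), con)
  invisible(path)
}

format_num <- function(x) formatC(x, format = "g", digits = 17)

#' Read and write MEME minimal motif files
#'
#' Reads position weight matrices (PWMs) from MEME minimal motif format.
#' Each `MOTIF` block must carry a `letter-probability matrix` over the
#' 4-letter DNA alphabet; every row must sum to 1 within `1e-3` (and is
#' renormalized exactly).  Background letter frequencies in the file are
#' used unless overridden.
#'
#' @param path path to a MEME minimal format file.
#' @param background optional 4-vector of background frequencies
#'   (A, C, G, T) overriding the file's `Background letter frequencies`
#'   block; see [pwm()] for the two standard choices.
#' @param pseudocount floor applied to zero probability cells before
#'   taking log-odds.
#' @return `read_pwm_meme()`: a list of [pwm()] objects, in file order.
#' @export
read_pwm_meme <- function(path, background = NULL, pseudocount = 1e-3) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  bg_file <- NULL
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(lines[bg_at[1L] + 1L], "\\s+")[[1L]]
    freq <- as.numeric(toks[c(FALSE, TRUE)])
    names(freq) <- toks[c(TRUE, FALSE)]
    bg_file <- unname(freq[c("A", "C", "G", "T")])
    if (anyNA(bg_file)) stop("malformed background frequency line")
  }
  bg <- if (!is.null(background)) background else
    if (!is.null(bg_file)) bg_file else rep(0.25, 4)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF blocks found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    block <- lines[starts[k]:ends[k]]
    name <- strsplit(block[1L], "\\s+")[[1L]][2L]
    if (is.na(name) || !nzchar(name)) stop("MOTIF block without a name")
    hdr <- grep("^letter-probability matrix", block)
    if (!length(hdr)) stop("motif '", name, "': missing letter-probability matrix")
    al <- regmatches(block[hdr], regexec("alength=\\s*(\\d+)", block[hdr]))[[1L]][2L]
    if (!is.na(al) && as.integer(al) != 4L)
      stop("motif '", name, "': alphabet length must be 4, got ", al)
    rows <- block[-seq_len(hdr)]
    rows <- rows[grepl("^[0-9.eE+ -]+$", rows) & nzchar(rows)]
    if (!length(rows)) stop("motif '", name, "': empty probability matrix")
    probs <- do.call(rbind, lapply(rows, function(r) {
      v <- as.numeric(strsplit(r, "\\s+")[[1L]])
      if (length(v) != 4L)
        stop("motif '", name, "': probability row must have 4 columns")
      v
    }))
    sums <- rowSums(probs)
    if (any(abs(sums - 1) > 1e-3))
      stop(sprintf("motif '%s': probability row %d sums to %.4f, not 1",
                   name, which(abs(sums - 1) > 1e-3)[1L],
                   sums[which(abs(sums - 1) > 1e-3)[1L]]))
    pwm(name, probs / sums, background = bg, pseudocount = pseudocount)
  })
}

#' @rdname read_pwm_meme
#' @param pwms a list of [pwm()] objects.
#' @return `write_pwm_meme()`: `path`, invisibly.
#' @export
write_pwm_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1L]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(c(rbind(c("A", "C", "G", "T"), format_num(bg))),
                     collapse = " "), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(p$probs)), con)
    for (i in seq_len(nrow(p$probs)))
      writeLines(paste(format_num(p$probs[i, ]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Flat key-value configuration files
#'
#' A minimal `key: value` configuration format (a flat subset of YAML).
#' Values are parsed as numeric when possible, as logical for
#' `true`/`false`, and split on commas into vectors.
#'
#' @param path file path.
#' @return `read_config()`: a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    out[[m[2L]]] <- parse_config_value(m[3L])
  }
  out
}

parse_config_value <- function(s) {
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
  if (!length(parts)) return("")
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(num)
  low <- tolower(parts)
  if (all(low %in% c("true", "false"))) return(low == "true")
  if (length(parts) == 1L) parts else parts
}

#' @rdname read_config
#' @param x a named list of scalar or vector values.
#' @return `write_config()`: `path`, invisibly.
#' @export
write_config <- function(x, path) {
  fmt <- function(v) paste(if (is.numeric(v)) format_num(v) else as.character(v),
                           collapse = ", ")
  writeLines(sprintf("%s: %s", names(x), vapply(x, fmt, character(1))), path)
  invisible(path)
}
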
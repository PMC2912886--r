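#' Position weight matrices
#'
#' A `pwm` bundles a motif's per-position base probabilities with a
#' background frequency model and the derived log-odds (base 2, i.e. bits)
#' scoring matrix.  `s_max`, the maximal attainable score (sum of the
#' largest log-odds entry in every column of the motif), is used to
#' normalize site scores into affinities `q = score / s_max` in `(0, 1]`.
#'
#' Two standard backgrounds are supported via [pwm_background()]:
#' `"uniform"` (0.25 each) and `"dmel"`, the D. melanogaster-specific
#' frequencies F_A = F_T = 0.297, F_C = F_G = 0.203.
#'
#' @param name motif/TF name.
#' @param probs L-by-4 matrix of base probabilities, columns in order
#'   A, C, G, T; every row must sum to 1 within `1e-6` (renormalize on
#'   read if needed).
#' @param background 4-vector of background frequencies summing to 1, or a
#'   mode name accepted by [pwm_background()].
#' @param pseudocount floor substituted for zero probability cells before
#'   taking log-odds, so scores stay finite.
#' @return An object of class `pwm`: a list with elements `name`, `probs`,
#'   `background`, `log_odds` (L-by-4, bits) and `s_max` (bits).
#' @export
pwm <- function(name, probs, background = "uniform", pseudocount = 1e-3) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1L) stop("PWM must have at least one position")
  if (any(probs < 0)) stop("PWM probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("PWM probability rows must sum to 1 (tolerance 1e-6)")
  if (is.character(background)) background <- pwm_background(background)
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6)
    stop("background must be a 4-vector summing to 1")
  p <- probs
  p[p == 0] <- pseudocount
  lo <- log2(sweep(p, 2L, background, "/"))
  colnames(probs) <- colnames(lo) <- c("A", "C", "G", "T")
  s_max <- sum(apply(lo, 1L, max))
  if (s_max <= 0)
    stop("PWM '", name, "' has non-positive maximal score (no information)")
  structure(list(name = name, probs = probs, background = background,
                 log_odds = lo, s_max = s_max),
            class = "pwm")
}

#' @rdname pwm
#' @param mode `"uniform"` or `"dmel"`.
#' @export
pwm_background <- function(mode = c("uniform", "dmel")) {
  mode <- match.arg(mode)
  switch(mode,
         uniform = rep(0.25, 4),
         dmel = c(0.297, 0.203, 0.203, 0.297))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, s_max %.2f bits, consensus %s\n",
              x$name, nrow(x$probs), x$s_max, pwm_consensus(x)))
  invisible(x)
}

#' @rdname pwm
#' @param x a `pwm`.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$probs, 1L, which.max)], collapse = "")
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_dna <- function(seq) {
  unname(DNA_CODE[strsplit(toupper(seq), "", fixed = TRUE)[[1L]]])
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (upper case).
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(seq)), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Score one window with a PWM
#'
#' Sum over motif positions of the log-odds (bits) score of the base
#' observed at that position; the independent-position additivity is the
#' defining property of PWM scoring.
#'
#' @param pwm a [pwm()].
#' @param window DNA string of exactly the motif width.
#' @return score in bits.
#' @export
log_odds_score <- function(pwm, window) {
  L <- nrow(pwm$log_odds)
  if (nchar(window) != L)
    stop(sprintf("window length %d does not match PWM width %d",
                 nchar(window), L))
  code <- encode_dna(window)
  if (anyNA(code))
    stop("window contains a non-ACGT base: ", window)
  sum(pwm$log_odds[cbind(seq_len(L), code)])
}

# Scores of every window of one encoded strand; windows containing an
# ambiguous base come back NA.
scan_strand_scores <- function(lo, code) {
  L <- nrow(lo)
  n <- length(code)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  scores <- numeric(nw)
  na <- rep(FALSE, nw)
  for (i in seq_len(L)) {
    b <- code[i:(i + nw - 1L)]
    na <- na | is.na(b)
    b[is.na(b)] <- 1L
    scores <- scores + lo[i, b]
  }
  scores[na] <- NA_real_
  scores
}

#' Scan a CRM sequence for high-scoring sites of one PWM
#'
#' Every window on both strands whose log-odds score reaches the threshold
#' `t` (in bits) becomes a predicted TF binding site (TFBS).  The minus
#' strand is scored on the reverse complement; overlapping sites are all
#' retained.  Coordinates are 0-based, half-open `[start, start + L)` on
#' the forward strand of the CRM.  Windows containing an ambiguous base are
#' skipped (their count is available as attribute `skipped`).
#'
#' @param pwm a [pwm()].
#' @param seq CRM DNA string.
#' @param t score threshold in bits (default 9, the standard scan setting
#'   for this dataset).
#' @return data frame of class `tfbs` with columns `tf`, `start`, `strand`,
#'   `width`, `score` (bits) and `q` (score normalized by `s_max`).  Empty
#'   (zero-row) when the sequence is shorter than the motif or nothing
#'   reaches threshold.
#' @export
scan_crm <- function(pwm, seq, t = 9) {
  stopifnot(is.finite(t))
  L <- nrow(pwm$log_odds)
  seq <- toupper(seq)
  code_f <- suppressWarnings(unname(DNA_CODE[strsplit(seq, "", fixed = TRUE)[[1L]]]))
  n <- length(code_f)
  empty <- tfbs_frame(character(0), integer(0), character(0), integer(0),
                      numeric(0), numeric(0))
  if (n < L) return(empty)
  fwd <- scan_strand_scores(pwm$log_odds, code_f)
  # site at rc-offset s corresponds to forward start n - L - s (0-based)
  code_r <- rev(5L - code_f)                       # complement of reversed
  rev_sc <- scan_strand_scores(pwm$log_odds, code_r)
  skipped <- sum(is.na(fwd)) + sum(is.na(rev_sc))
  hit_f <- which(!is.na(fwd) & fwd >= t)
  hit_r <- which(!is.na(rev_sc) & rev_sc >= t)
  out <- tfbs_frame(
    tf = rep(pwm$name, length(hit_f) + length(hit_r)),
    start = c(hit_f - 1L, n - L - (hit_r - 1L)),
    strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
    width = rep(L, length(hit_f) + length(hit_r)),
    score = c(fwd[hit_f], rev_sc[hit_r]),
    q = c(fwd[hit_f], rev_sc[hit_r]) / pwm$s_max)
  out <- out[order(out$start, out$strand, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

tfbs_frame <- function(tf, start, strand, width, score, q) {
  structure(data.frame(tf = tf, start = as.integer(start), strand = strand,
                       width = as.integer(width), score = score, q = q,
                       stringsAsFactors = FALSE),
            class = c("tfbs", "data.frame"))
}

#' Build a TFBS-map for a set of CRMs
#'
#' Scans every CRM with every PWM and collects the predicted sites, sorted
#' by start position, into a per-CRM map — the discrete site representation
#' the thermodynamic model consumes.
#'
#' @param crms a [sequence_set()] of DNA sequences.
#' @param pwms list of [pwm()] objects with distinct names.
#' @param t scan threshold in bits.
#' @param warn warn about CRMs with no sites at all.
#' @return An object of class `tfbs_map`: a named list (one element per
#'   CRM, input order) of `tfbs` data frames.
#' @export
build_tfbs_map <- function(crms, pwms, t = 9, warn = TRUE) {
  stopifnot(inherits(crms, "sequence_set"))
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  nm <- vapply(pwms, function(p) p$name, character(1))
  if (anyDuplicated(nm))
    stop("PWM names must be distinct: ", paste(nm[duplicated(nm)], collapse = ", "))
  out <- lapply(names(crms), function(id) {
    hits <- lapply(pwms, scan_crm, seq = crms[[id]], t = t)
    df <- if (length(hits))
      do.call(rbind, c(hits, list(make.row.names = FALSE)))
    else
      tfbs_frame(character(0), integer(0), character(0), integer(0),
                 numeric(0), numeric(0))
    df <- df[order(df$start, df$strand, df$tf), , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("tfbs", "data.frame")
    if (warn && nrow(df) == 0L)
      warning("CRM '", id, "' has no predicted sites for any TF")
    df
  })
  structure(stats::setNames(out, names(crms)), class = "tfbs_map")
}

#' @export
print.tfbs_map <- function(x, ...) {
  n <- vapply(x, nrow, integer(1))
  cat(sprintf("tfbs_map: %d CRM(s), %d site(s) total (%.1f per CRM)\n",
              length(x), sum(n), mean(n)))
  invisible(x)
}

#' Read and write TFBS-maps as TSV
#'
#' Columns: `crm`, `tf`, `start` (0-based), `strand`, `width`,
#' `score_bits`, `q`.
#'
#' @param x a `tfbs_map`.
#' @param path file path.
#' @param comment optional comment line(s) written with a leading `#`.
#' @export
write_tfbs_map <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "tfbs_map"))
  rows <- do.call(rbind, lapply(names(x), function(id) {
    d <- x[[id]]
    if (!nrow(d)) return(NULL)
    cbind(crm = id, d)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines("crm\ttf\tstart\tstrand\twidth\tscore_bits\tq", con)
  if (!is.null(rows))
    writeLines(sprintf("%s\t%s\t%d\t%s\t%d\t%s\t%s", rows$crm, rows$tf,
                       rows$start, rows$strand, rows$width,
                       format_num(rows$score), format_num(rows$q)), con)
  invisible(path)
}

#' @rdname write_tfbs_map
#' @param crm_ids CRM ids defining map order (CRMs absent from the file get
#'   empty site lists); defaults to the ids present in the file.
#' @export
read_tfbs_map <- function(path, crm_ids = NULL) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("crm", "tf", "start", "strand", "width", "score_bits", "q")
  if (!all(need %in% names(d)))
    stop("TFBS-map TSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(crm_ids)) crm_ids <- unique(d$crm)
  out <- lapply(crm_ids, function(id) {
    s <- d[d$crm == id, , drop = FALSE]
    df <- tfbs_frame(s$tf, s$start, s$strand, s$width, s$score_bits, s$q)
    df[order(df$start, df$strand, df$tf), , drop = FALSE]
  })
  structure(stats::setNames(out, crm_ids), class = "tfbs_map")
}
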
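#' CRM-by-configuration CC matrices
#'
#' For `n` TFs there are `2^n` role configurations.  The CC matrix records,
#' for every CRM and every configuration, the mean-over-repeats correlation
#' achieved when the model is trained on that CRM alone under that
#' configuration.  All role-determining methods read from this matrix.
#'
#' @param dataset a [crm_dataset()].
#' @param schedule an [sa_schedule()]; every cell derives its own seed from
#'   the schedule's master seed, so the matrix is deterministic.
#' @param bounds fit bounds, as [default_bounds()].
#' @param d quench distance in bp.
#' @param guard maximum panel size (the column count is `2^n`).
#' @param progress print a line per CRM as cells complete.
#' @return an object of class `cc_matrix`: list with `cc` (CRMs x configs
#'   matrix), `crms`, `configs` (integer indices `0:(2^n - 1)`), `panel`.
#' @export
build_cc_matrix <- function(dataset, schedule = sa_schedule(),
                            bounds = default_bounds(), d = 100, guard = 10L,
                            progress = FALSE) {
  n <- length(dataset$panel$names)
  if (n > guard)
    stop("panel of ", n, " TFs gives 2^", n,
         " configurations; use a subset (guard = ", guard, ")")
  configs <- 0:(2^n - 1L)
  ids <- names(dataset$crms)
  cc <- matrix(NA_real_, length(ids), length(configs),
               dimnames = list(ids, as.character(configs)))
  for (i in seq_along(ids)) {
    sub <- subset_crms(dataset, ids[i])
    for (j in seq_along(configs)) {
      cell_seed <- derive_seed(schedule$seed,
                               100003 * ((i - 1L) * length(configs) + j - 1L) + 1)
      sch <- sa_schedule(schedule$T0, schedule$alpha, schedule$iterations,
                         schedule$repeats, cell_seed,
                         sigma = if (is.null(schedule$sigma)) 0.5
                                 else schedule$sigma)
      cc[i, j] <- sa_fit(sub, configs[j], sch, bounds, d = d)$mean_cc
    }
    if (progress)
      message(sprintf("cc_matrix: CRM %s (%d/%d) done", ids[i], i, length(ids)))
  }
  structure(list(cc = cc, crms = ids, configs = configs,
                 panel = dataset$panel),
            class = "cc_matrix")
}

#' @rdname build_cc_matrix
#' @param cc a CRMs-by-configurations numeric matrix (columns in config
#'   index order `0 .. 2^n - 1`).
#' @param panel the [tf_panel()] the configuration bits refer to.
#' @export
cc_matrix <- function(cc, panel) {
  cc <- as.matrix(cc)
  n <- length(panel$names)
  if (ncol(cc) != 2^n)
    stop(sprintf("expected 2^%d = %d columns, got %d", n, 2^n, ncol(cc)))
  if (any(!is.finite(cc)) || any(cc < -1 - 1e-9) || any(cc > 1 + 1e-9))
    stop("CC values must be finite and in [-1, 1]")
  if (is.null(rownames(cc))) rownames(cc) <- paste0("crm", seq_len(nrow(cc)))
  structure(list(cc = cc, crms = rownames(cc), configs = 0:(2^n - 1L),
                 panel = panel),
            class = "cc_matrix")
}

#' @export
print.cc_matrix <- function(x, ...) {
  cat(sprintf("cc_matrix: %d CRMs x %d configurations (%d TFs)\n",
              nrow(x$cc), ncol(x$cc), length(x$panel$names)))
  invisible(x)
}

#' Subset a dataset to a set of CRMs
#'
#' @param dataset a [crm_dataset()].
#' @param ids CRM ids to keep.
#' @return a [crm_dataset()] over the selected CRMs.
#' @export
subset_crms <- function(dataset, ids) {
  stopifnot(all(ids %in% names(dataset$crms)))
  sites <- structure(dataset$sites[ids], class = "tfbs_map")
  obs <- profile_set(dataset$observed$axis,
                     dataset$observed$profiles[ids, , drop = FALSE])
  crm_dataset(dataset$crms[ids], sites, dataset$concentrations, obs,
              dataset$panel)
}

method_result <- function(method, chosen_configs, per_crm_config, calls) {
  structure(list(method = method,
                 chosen_configs = sort(unique(as.integer(chosen_configs))),
                 per_crm_config = per_crm_config, calls = calls),
            class = "method_result")
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf("method_result [%s]: %d configuration(s), %d call(s) (%d strong)\n",
              x$method, length(x$chosen_configs), nrow(x$calls),
              sum(x$calls$strong)))
  invisible(x)
}

# Maximum |CC difference| over all config pairs differing only in tf's bit,
# per CRM, with its sign (positive = activator better).  Rows CRMs, cols TFs.
pairwise_role_deltas <- function(ccm) {
  n <- length(ccm$panel$names)
  m <- nrow(ccm$cc)
  act_idx <- lapply(seq_len(n), function(t) which(bitwAnd(ccm$configs, 2^(t - 1L)) > 0))
  delta <- matrix(0, m, n, dimnames = list(ccm$crms, ccm$panel$names))
  for (t in seq_len(n)) {
    a <- act_idx[[t]]
    r <- a - 2^(t - 1L) # partner columns: same config with tf t as repressor
    d <- ccm$cc[, a, drop = FALSE] - ccm$cc[, r, drop = FALSE]
    pick <- max.col(abs(d), ties.method = "first")
    delta[, t] <- d[cbind(seq_len(m), pick)]
  }
  delta
}

role_calls_from_config <- function(ccm, per_crm_config, epsilon) {
  delta <- pairwise_role_deltas(ccm)
  tfs <- ccm$panel$names
  do.call(rbind, lapply(ccm$crms, function(crm) {
    roles <- roles_from_index(per_crm_config[[crm]], length(tfs))
    na <- abs(delta[crm, ]) < epsilon
    data.frame(crm = crm, tf = tfs,
               role = ifelse(na, NA_character_,
                             ifelse(roles > 0, "ACT", "REP")),
               strong = !na, delta_cc = NA_real_,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' SMALLEST-OPTIMAL role-determining method
#'
#' Finds, for each CRM, the configurations within `tie_tol` of its row
#' maximum ("optimal" for that CRM), then selects a minimum-cardinality
#' set of configurations containing at least one optimal configuration for
#' every CRM (exact minimum set cover, lexicographically smallest on
#' ties).  Each CRM is assigned the smallest-index chosen configuration
#' that is optimal for it; a TF's per-CRM role comes from that
#' configuration, except that the role is `NA` when no pair of
#' configurations differing only in that TF changes the CRM's CC by at
#' least `epsilon`.  Non-`NA` calls are "strong".
#'
#' @param ccm a [cc_matrix()].
#' @param epsilon minimum CC difference for a TF to matter on a CRM.
#' @param tie_tol absolute tolerance for ties with the row maximum.
#' @return a `method_result`.
#' @export
smallest_optimal <- function(ccm, epsilon = 0.1, tie_tol = 1e-9) {
  stopifnot(inherits(ccm, "cc_matrix"))
  m <- nrow(ccm$cc)
  opt <- lapply(seq_len(m), function(i) {
    which(ccm$cc[i, ] >= max(ccm$cc[i, ]) - tie_tol)
  })
  chosen_cols <- min_set_cover(opt, ncol(ccm$cc))
  per_crm <- vapply(seq_len(m), function(i) {
    ccm$configs[min(intersect(chosen_cols, opt[[i]]))]
  }, integer(1))
  names(per_crm) <- ccm$crms
  calls <- role_calls_from_config(ccm, per_crm, epsilon)
  method_result("smallest_optimal", ccm$configs[chosen_cols], per_crm, calls)
}

# Exact minimum set cover over tiny instances: universe = CRMs, candidate
# sets = configuration columns covering the CRMs they are optimal for.
# Branch and bound; deterministic lexicographically-smallest tie-break.
min_set_cover <- function(opt_sets, n_cols) {
  m <- length(opt_sets)
  covers <- lapply(seq_len(n_cols), function(j)
    which(vapply(opt_sets, function(s) j %in% s, logical(1))))
  useful <- which(lengths(covers) > 0)
  best <- NULL
  max_cover <- max(lengths(covers))
  recurse <- function(chosen, covered) {
    if (length(covered) == m) {
      cand <- sort(chosen)
      if (is.null(best) || length(cand) < length(best) ||
          (length(cand) == length(best) && lex_less(cand, best)))
        best <<- cand
      return(invisible())
    }
    need <- ceiling((m - length(covered)) / max_cover)
    if (!is.null(best) && length(chosen) + need > length(best)) return(invisible())
    # branch on the uncovered CRM with the fewest optimal configs
    remaining <- setdiff(seq_len(m), covered)
    counts <- vapply(remaining, function(i) length(opt_sets[[i]]), integer(1))
    target <- remaining[which.min(counts)]
    for (j in sort(intersect(opt_sets[[target]], useful))) {
      recurse(c(chosen, j), union(covered, covers[[j]]))
    }
    invisible()
  }
  recurse(integer(0), integer(0))
  if (is.null(best)) stop("no covering set exists (a CRM has no optimal config)")
  best
}

lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' BEST-N role-determining method
#'
#' Exact search for the set of `n` configurations maximizing the total CC
#' `sum over CRMs of max over the chosen configurations`, with each CRM
#' assigned its best in-set configuration.  Every call is "strong" (the
#' method always commits to a role).  Exhaustive exactness is preserved by
#' branch-and-bound with suffix-maximum pruning; `n` is capped at 4.
#'
#' @param ccm a [cc_matrix()].
#' @param n number of configurations to select (1..4).
#' @return a `method_result`; the achieved total is in attribute
#'   `total_cc` and the per-CRM mean in attribute `mean_cc`.
#' @export
best_n <- function(ccm, n = 4L) {
  stopifnot(inherits(ccm, "cc_matrix"))
  n <- as.integer(n)
  if (n < 1L || n > 4L) stop("best_n is exact and supported only for n in 1..4")
  cc <- ccm$cc
  C <- ncol(cc)
  n <- min(n, C)
  # suffix row maxima: suff[[j]] = per-CRM max over columns j..C
  suff <- matrix(-Inf, nrow(cc), C + 1L)
  for (j in C:1) suff[, j] <- pmax(cc[, j], suff[, j + 1L])
  best_total <- -Inf; best_set <- NULL
  dfs <- function(start, chosen, curmax) {
    r <- n - length(chosen)
    if (r == 0L) {
      tot <- sum(curmax)
      if (tot > best_total) { best_total <<- tot; best_set <<- chosen }
      return(invisible())
    }
    if (start > C - r + 1L) return(invisible())
    ub <- sum(pmax(curmax, suff[, start]))
    if (ub <= best_total) return(invisible())
    for (j in start:(C - r + 1L)) {
      dfs(j + 1L, c(chosen, j), pmax(curmax, cc[, j]))
    }
    invisible()
  }
  dfs(1L, integer(0), rep(-Inf, nrow(cc)))
  sub <- cc[, best_set, drop = FALSE]
  assign_col <- best_set[max.col(sub, ties.method = "first")]
  per_crm <- stats::setNames(ccm$configs[assign_col], ccm$crms)
  tfs <- ccm$panel$names
  calls <- do.call(rbind, lapply(ccm$crms, function(crm) {
    roles <- roles_from_index(per_crm[[crm]], length(tfs))
    data.frame(crm = crm, tf = tfs,
               role = ifelse(roles > 0, "ACT", "REP"),
               strong = TRUE, delta_cc = NA_real_,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out <- method_result("best_n", ccm$configs[best_set], per_crm, calls)
  attr(out, "total_cc") <- best_total
  attr(out, "mean_cc") <- best_total / nrow(cc)
  out
}

#' SENSITIVITY role-determining method
#'
#' For every CRM-TF pair, examines all `2^(n-1)` pairs of configurations
#' that differ only in that TF's role and finds the pair with the largest
#' absolute CC difference.  The TF is assigned the role whose side of that
#' pair fits better (positive difference means activator); if the largest
#' absolute difference does not exceed `na_threshold` no role is assigned
#' (`NA`).  A call is "strong" if the absolute difference exceeds
#' `strong_threshold`.
#'
#' @param ccm a [cc_matrix()].
#' @param na_threshold below-or-equal this absolute CC difference the role
#'   is `NA`.
#' @param strong_threshold strictly above this the call is "strong".
#' @return a `method_result`; `delta_cc` carries the signed maximal
#'   difference.  Per-CRM configurations are assembled from the per-TF
#'   calls with `NA` falling back to the panel's literature role.
#' @export
sensitivity <- function(ccm, na_threshold = 0.1, strong_threshold = 0.1) {
  stopifnot(inherits(ccm, "cc_matrix"))
  delta <- pairwise_role_deltas(ccm)
  tfs <- ccm$panel$names
  lit <- ccm$panel$literature_roles
  calls <- do.call(rbind, lapply(ccm$crms, function(crm) {
    d <- delta[crm, ]
    na <- abs(d) <= na_threshold
    data.frame(crm = crm, tf = tfs,
               role = ifelse(na, NA_character_, ifelse(d > 0, "ACT", "REP")),
               strong = abs(d) > strong_threshold,
               delta_cc = unname(d),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  per_crm <- vapply(ccm$crms, function(crm) {
    d <- delta[crm, ]
    roles <- ifelse(abs(d) <= na_threshold, lit[tfs], ifelse(d > 0, 1, -1))
    index_from_roles(roles)
  }, numeric(1))
  per_crm <- stats::setNames(as.integer(per_crm), ccm$crms)
  method_result("sensitivity", unique(per_crm), per_crm, calls)
}

#' Summarize per-CRM calls into a single role per TF
#'
#' Counts, among a method's non-`NA` calls for a TF, the share of CRMs
#' favouring each role.  If more than `theta` of them favour activation
#' the TF is `"+"`; if more than `theta` favour repression it is `"-"`;
#' otherwise it switches roles (`"s"`).  A TF with no non-`NA` call is
#' `"s"` with confidence 0.
#'
#' @param result a `method_result`.
#' @param theta majority fraction in `(0.5, 1]`; default 2/3.
#' @return data frame with one row per TF: `tf`, `role`, counts of
#'   ACT/REP calls and strong calls, and `confidence` (strong calls
#'   supporting the assigned label; for `"s"`, all strong calls).
#' @export
summarize_tf_roles <- function(result, theta = 2 / 3) {
  stopifnot(inherits(result, "method_result"), theta > 0.5, theta <= 1)
  calls <- result$calls
  tfs <- unique(calls$tf)
  rows <- lapply(tfs, function(tf) {
    x <- calls[calls$tf == tf, ]
    n_act <- sum(x$role == "ACT", na.rm = TRUE)
    n_rep <- sum(x$role == "REP", na.rm = TRUE)
    ns_act <- sum(x$strong & !is.na(x$role) & x$role == "ACT")
    ns_rep <- sum(x$strong & !is.na(x$role) & x$role == "REP")
    tot <- n_act + n_rep
    role <- if (tot == 0) "s"
    else if (n_act / tot > theta) "+"
    else if (n_rep / tot > theta) "-"
    else "s"
    conf <- switch(role, "+" = ns_act, "-" = ns_rep, "s" = ns_act + ns_rep)
    if (tot == 0) conf <- 0L
    data.frame(tf = tf, role = role, n_act = n_act, n_rep = n_rep,
               n_strong_act = ns_act, n_strong_rep = ns_rep,
               confidence = as.integer(conf), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Majority-vote ensemble over the three role-determining methods
#'
#' Per TF, takes the majority label among the three per-method summaries
#' (`"+"`, `"-"`, `"s"`); with no 2-of-3 majority the TF is declared a
#' switcher (`"s"`).  Confidence is the total number of strong per-CRM
#' calls supporting the final label, summed across methods (a package
#' substitute for the original, undefined confidence figure).
#'
#' @param summaries list of exactly three [summarize_tf_roles()] data
#'   frames over the same panel.
#' @return an object of class `role_summary`: data frame `tf`, `role`,
#'   `confidence`.
#' @export
ensemble_vote <- function(summaries) {
  if (length(summaries) != 3L)
    stop("ensemble_vote needs exactly three method summaries")
  tfs <- summaries[[1L]]$tf
  for (s in summaries[-1L])
    if (!identical(s$tf, tfs)) stop("method summaries cover different panels")
  rows <- lapply(seq_along(tfs), function(i) {
    labs <- vapply(summaries, function(s) s$role[i], character(1))
    tab <- table(labs)
    role <- if (max(tab) >= 2L) names(tab)[which.max(tab)] else "s"
    conf <- sum(vapply(summaries, function(s) {
      switch(role,
             "+" = s$n_strong_act[i],
             "-" = s$n_strong_rep[i],
             "s" = s$n_strong_act[i] + s$n_strong_rep[i])
    }, numeric(1)))
    data.frame(tf = tfs[i], role = role, confidence = as.integer(conf),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("role_summary", "data.frame"))
}

#' @export
print.role_summary <- function(x, ...) {
  cat("role_summary (+ activator, - repressor, s switch):\n")
  print.data.frame(x)
  invisible(x)
}

#' Classify motif-enrichment p-values
#'
#' Applies the over/under/background rules to a pair of enrichment
#' p-values for a TF's binding sites in an "activator" and a "repressor"
#' CRM set: over-represented if `p < alpha` (default 0.01),
#' under-represented if `p > beta` (default 0.99), background otherwise.
#' The TF is differentially enriched iff exactly one set is
#' over-represented, the other is under-represented or background, and
#' the p-values differ by more than `delta` (default 0.2).  `NA` means
#' the set was not tested (and blocks a differential call).
#'
#' @param p_act,p_rep p-values in `[0, 1]`, or `NA` for untested;
#'   vectorized.
#' @param alpha over-representation threshold.
#' @param beta under-representation threshold.
#' @param delta minimum p-value difference for a differential call.
#' @return data frame with `p_act`, `p_rep`, `status_act`, `status_rep`
#'   (each `over`/`under`/`background`/`untested`) and `differential`.
#' @export
enrichment_call <- function(p_act, p_rep, alpha = 0.01, beta = 0.99,
                            delta = 0.2) {
  status <- function(p) {
    ifelse(is.na(p), "untested",
           ifelse(p < alpha, "over", ifelse(p > beta, "under", "background")))
  }
  ok <- function(p) is.na(p) | (p >= 0 & p <= 1)
  if (any(!ok(p_act)) || any(!ok(p_rep)))
    stop("p-values must lie in [0, 1] (or NA for untested)")
  sa <- status(p_act); sr <- status(p_rep)
  diff_ok <- !is.na(p_act) & !is.na(p_rep) & abs(p_act - p_rep) > delta
  differential <- diff_ok &
    ((sa == "over" & sr %in% c("under", "background")) |
     (sr == "over" & sa %in% c("under", "background")))
  data.frame(p_act = p_act, p_rep = p_rep, status_act = sa, status_rep = sr,
             differential = differential, stringsAsFactors = FALSE)
}

#' Classify a whole enrichment p-value table
#'
#' Reads a TSV with columns `tf` then one `<set>_act` / `<set>_rep` column
#' pair per comparison (empty cells = untested) and applies
#' [enrichment_call()] to every TF-comparison pair.
#'
#' @param path TSV path, or a data frame in that layout.
#' @inheritParams enrichment_call
#' @return long-format data frame: `tf`, `comparison`, plus the
#'   [enrichment_call()] columns.
#' @export
classify_enrichment_table <- function(path, alpha = 0.01, beta = 0.99,
                                      delta = 0.2) {
  d <- if (is.data.frame(path)) path
  else utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"tf" %in% names(d)) stop("enrichment table needs a 'tf' column")
  act_cols <- grep("_act$", names(d), value = TRUE)
  out <- lapply(act_cols, function(ac) {
    comp <- sub("_act$", "", ac)
    rc <- paste0(comp, "_rep")
    if (!rc %in% names(d)) stop("missing column ", rc)
    cbind(tf = d$tf, comparison = comp,
          enrichment_call(as.numeric(d[[ac]]), as.numeric(d[[rc]]),
                          alpha, beta, delta))
  })
  do.call(rbind, out)
}

#' Bonferroni correction
#'
#' Multiplies a p-value by the number of tests, capped at 1 (e.g. an
#' uncorrected p-value of 0.001 over 76 motifs corrects to 0.076).
#'
#' @param p p-value(s).
#' @param m number of tests.
#' @return corrected p-value(s).
#' @export
bonferroni_correct <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(p * m, 1)
}
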
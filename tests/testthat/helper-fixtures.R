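# Shared in-code fixtures; everything is generated at test time.

# A sharp 3-position PWM with consensus ACG under uniform background.
fix_pwm_acg <- function(p = 0.97, name = "acg") {
  probs <- matrix((1 - p) / 3, 3, 4)
  probs[cbind(1:3, c(1, 2, 3))] <- p
  pwm(name, probs, background = "uniform")
}

# A random PWM of the given width (rows Dirichlet-ish via normalized gamma).
fix_random_pwm <- function(width, name = "rnd", background = "uniform") {
  probs <- matrix(stats::rgamma(width * 4, 1), width, 4)
  probs <- probs / rowSums(probs)
  pwm(name, probs, background = background)
}

# Tiny two-TF world used by thermo/sa unit tests: one activator with an
# anterior gradient, one repressor with a central bump, one site each.
fix_tiny_dataset <- function(noise_sd = 0, seed = 7, n_crms = 2) {
  spec <- generator_spec(
    n_crms = n_crms, crm_length = 300, n_positions = 30,
    tf_specs = list(
      A = list(shape = "anterior_exp", lambda = 30,
               consensus = "ACCGTTAC", p = 0.9, role = "+"),
      R = list(shape = "gaussian_bump", mu = 40, sigma = 10,
               consensus = "TTGCACGA", p = 0.9, role = "-")),
    noise_sd = noise_sd, dual_tf = NULL, cluster_span = 80, seed = seed)
  make_synthetic_dataset(spec)
}

# Random CC matrix over n_tfs with values discretized to `levels` distinct
# CC values (discretization creates the row-optimum ties that make the
# set-cover instances non-trivial).
fix_random_ccm <- function(n_crms, n_tfs, levels = 0) {
  vals <- stats::runif(n_crms * 2^n_tfs, -1, 1)
  if (levels > 0) vals <- round(vals * levels) / levels
  cc_matrix(matrix(vals, n_crms, 2^n_tfs),
            tf_panel(paste0("tf", seq_len(n_tfs)),
                     rep(c("+", "-"), length.out = n_tfs)))
}

# --- independent brute-force oracles ------------------------------------

# Exhaustive BEST-N: enumerate every n-subset of columns.
oracle_best_n <- function(cc, n) {
  combos <- utils::combn(ncol(cc), n)
  totals <- apply(combos, 2, function(js)
    sum(apply(cc[, js, drop = FALSE], 1, max)))
  best <- max(totals)
  # lexicographically smallest among maxima (combn enumerates in lex order)
  list(total = best, set = combos[, which(totals == best)[1L]])
}

# Exhaustive minimum set cover: try all subsets by increasing size.
oracle_min_cover <- function(opt_sets, n_cols) {
  m <- length(opt_sets)
  for (k in 1:n_cols) {
    combos <- utils::combn(n_cols, k)
    for (c_i in seq_len(ncol(combos))) {
      js <- combos[, c_i]
      if (all(vapply(opt_sets, function(s) any(js %in% s), logical(1))))
        return(js)
    }
  }
  stop("no cover")
}

# Exhaustive SENSITIVITY: loop over every configuration pair explicitly.
oracle_sensitivity_delta <- function(cc, n_tfs) {
  configs <- 0:(2^n_tfs - 1)
  delta <- matrix(0, nrow(cc), n_tfs)
  for (ci in seq_len(nrow(cc))) for (t in seq_len(n_tfs)) {
    best <- 0
    for (phi in configs) {
      if (bitwAnd(phi, 2^(t - 1)) == 0) next
      d <- cc[ci, phi + 1] - cc[ci, phi - 2^(t - 1) + 1]
      if (abs(d) > abs(best)) best <- d
    }
    delta[ci, t] <- best
  }
  delta
}

# Reference PWM window scorer: per-position lookup, one base at a time.
oracle_window_score <- function(pwm, window) {
  chars <- strsplit(window, "")[[1L]]
  p <- pwm$probs
  p[p == 0] <- 1e-3
  s <- 0
  for (i in seq_along(chars)) {
    j <- match(chars[i], c("A", "C", "G", "T"))
    s <- s + log2(p[i, j] / pwm$background[j])
  }
  unname(s)
}
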
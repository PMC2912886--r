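#' Synthetic gap-gene-style dataset specification
#'
#' Describes the stated world the generator emulates: `n` TF concentration
#' gradients along the AP axis, `m` CRM sequences with planted binding
#' sites, and per-CRM expression profiles produced by the forward
#' thermodynamic model plus Gaussian noise, with an optional planted
#' dual-function TF.  The desk-scale default — 4 TFs (16 configurations),
#' 8 CRMs of 500 bp, 50 AP positions, noise SD 0.05 — preserves the
#' structure of the real 8-TF / 44-CRM / 256-configuration dataset at a
#' size where the full CC-matrix pipeline runs in minutes.
#'
#' @param n_crms number of CRMs.
#' @param crm_length CRM length in bp.
#' @param n_positions AP grid size (axis spans 2-98 percent egg length).
#' @param tf_specs named list, one entry per TF:
#'   `list(shape, lambda | mu/sigma, consensus, p, role)` where `shape` is
#'   `"anterior_exp"`, `"posterior_exp"` or `"gaussian_bump"`, `consensus`
#'   the planted site sequence, `p` the per-position consensus probability
#'   of the PWM and `role` the literature role (`"+"`/`"-"`).
#' @param sites_per_tf planted sites per TF per CRM.
#' @param background `"uniform"`, `"dmel"` or a 4-vector of frequencies.
#' @param noise_sd SD of additive Gaussian expression noise (clipped at 0).
#' @param dual_tf name of the TF planted with dual function (`NULL` for
#'   none); it takes the activator role in `dual_act_crms` and its
#'   literature role elsewhere.
#' @param dual_act_crms indices of CRMs where `dual_tf` is an activator.
#' @param params ground-truth [model_params()] (default: K = 8,
#'   E_act = 5, E_rep = 0.9 for every TF, G0 = 5, R0 = 1, d = 100 bp).
#' @param scan_threshold bits; background sequence is rejection-sampled so
#'   that scanning at this threshold recovers exactly the planted sites.
#' @param min_gap minimum bp between planted sites.
#' @param cluster_span maximum bp spanned by a CRM's planted sites.  The
#'   default equals the quench distance `d`, so every repressor site can
#'   quench every activator site in its CRM — without this a planted
#'   repressor can be inert and its role unrecoverable (see the methods
#'   vignette).
#' @param seed master seed; all generator randomness derives from it.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(n_crms = 8, crm_length = 500, n_positions = 50,
                           tf_specs = default_tf_specs(),
                           sites_per_tf = 1, background = "uniform",
                           noise_sd = 0.05, dual_tf = "Mid",
                           dual_act_crms = seq_len(ceiling(n_crms / 2)),
                           params = NULL, scan_threshold = 9,
                           min_gap = 5, cluster_span = 100, seed = 1) {
  if (is.character(background)) background <- pwm_background(background)
  stopifnot(abs(sum(background) - 1) < 1e-6, noise_sd >= 0)
  tfs <- names(tf_specs)
  if (is.null(tfs)) stop("tf_specs must be a named list")
  if (!is.null(dual_tf) && !dual_tf %in% tfs)
    stop("dual_tf must be one of the panel TFs")
  if (is.null(params)) {
    k <- stats::setNames(rep(8, length(tfs)), tfs)
    params <- model_params(K = k,
                           E_act = stats::setNames(rep(5, length(tfs)), tfs),
                           E_rep = stats::setNames(rep(0.9, length(tfs)), tfs),
                           G0 = 5, R0 = 1, d = 100,
                           dual_tfs = if (is.null(dual_tf)) character(0) else dual_tf)
  }
  structure(list(n_crms = as.integer(n_crms),
                 crm_length = as.integer(crm_length),
                 n_positions = as.integer(n_positions),
                 tf_specs = tf_specs, sites_per_tf = as.integer(sites_per_tf),
                 background = background, noise_sd = noise_sd,
                 dual_tf = dual_tf,
                 dual_act_crms = as.integer(dual_act_crms),
                 params = params, scan_threshold = scan_threshold,
                 min_gap = as.integer(min_gap),
                 cluster_span = as.integer(cluster_span),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' @rdname generator_spec
#' @export
default_tf_specs <- function() {
  list(
    Ant  = list(shape = "anterior_exp", lambda = 35,
                consensus = "ACCGTTAC", p = 0.9, role = "+"),
    Post = list(shape = "posterior_exp", lambda = 35,
                consensus = "GATCCAGT", p = 0.9, role = "+"),
    Mid  = list(shape = "gaussian_bump", mu = 30, sigma = 8,
                consensus = "TTGCACGA", p = 0.9, role = "-"),
    Tail = list(shape = "gaussian_bump", mu = 70, sigma = 8,
                consensus = "CAGGTTCA", p = 0.9, role = "-"))
}

spec_panel <- function(spec) {
  tf_panel(names(spec$tf_specs),
           vapply(spec$tf_specs, function(s) s$role, character(1)))
}

spec_axis <- function(spec) seq(2, 98, length.out = spec$n_positions)

#' Generate TF concentration gradients
#'
#' Shapes (all scaled to maximum 1 over the axis, positions in percent
#' egg length): `anterior_exp(x) = exp(-(x - x_min) / lambda)`,
#' `posterior_exp` its mirror, and
#' `gaussian_bump(x) = exp(-(x - mu)^2 / (2 sigma^2))`.
#'
#' @param spec a [generator_spec()].
#' @return a [profile_set()] with one track per TF.
#' @export
make_concentration_profiles <- function(spec) {
  x <- spec_axis(spec)
  tracks <- lapply(spec$tf_specs, function(s) {
    v <- switch(s$shape,
                anterior_exp = exp(-(x - min(x)) / s$lambda),
                posterior_exp = exp(-(max(x) - x) / s$lambda),
                gaussian_bump = exp(-(x - s$mu)^2 / (2 * s$sigma^2)),
                stop("unknown gradient shape: ", s$shape))
    v / max(v)
  })
  profile_set(x, tracks)
}

#' @rdname generator_spec
#' @return `spec_pwms()`: the list of [pwm()] objects implied by the TF
#'   specs (consensus base probability `p`, others `(1 - p) / 3`).
#' @export
spec_pwms <- function(spec) {
  lapply(names(spec$tf_specs), function(tf) {
    s <- spec$tf_specs[[tf]]
    base <- match(strsplit(s$consensus, "")[[1L]], c("A", "C", "G", "T"))
    if (anyNA(base)) stop("consensus must be over ACGT")
    probs <- matrix((1 - s$p) / 3, length(base), 4L)
    probs[cbind(seq_along(base), base)] <- s$p
    pwm(tf, probs, background = spec$background)
  })
}

#' Sample a background DNA sequence
#'
#' Bases drawn i.i.d. at the given frequencies (A, C, G, T) — the null
#' model CRM background sequence is built from.
#'
#' @param n sequence length.
#' @param freqs 4-vector of base frequencies.
#' @return a DNA string.
#' @export
sample_background_seq <- function(n, freqs = pwm_background("dmel")) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

#' Generate CRM sequences with planted sites
#'
#' Background bases are drawn at the spec's frequencies; each TF's exact
#' consensus is planted `sites_per_tf` times per CRM (random strand and
#' order) as a compact site cluster: non-overlapping, at least `min_gap`
#' bp apart, spanning at most `cluster_span` bp, at a random offset within
#' the CRM.  Each CRM is rejection-sampled until scanning it at
#' `scan_threshold` bits recovers exactly the planted sites, so the
#' planted truth and the scanner agree by construction.
#'
#' @param spec a [generator_spec()].
#' @return list with `crms` (a [sequence_set()]) and `sites` (a
#'   `tfbs_map` of the planted truth, `q = 1` everywhere).
#' @export
make_crm_sequences <- function(spec) {
  set.seed(derive_seed(spec$seed, 1))
  pwms <- spec_pwms(spec)
  widths <- vapply(pwms, function(p) nrow(p$probs), integer(1))
  total_w <- sum(widths) * spec$sites_per_tf
  n_sites <- length(pwms) * spec$sites_per_tf
  if (total_w + (n_sites - 1) * spec$min_gap > min(spec$crm_length,
                                                   spec$cluster_span))
    stop("requested sites do not fit in the CRM / cluster span")
  ids <- sprintf("crm%02d", seq_len(spec$n_crms))
  crms <- character(spec$n_crms)
  site_frames <- vector("list", spec$n_crms)
  for (ci in seq_len(spec$n_crms)) {
    repeat {
      seqv <- strsplit(sample_background_seq(spec$crm_length, spec$background),
                       "", fixed = TRUE)[[1L]]
      plan <- plant_positions(spec$crm_length,
                              rep(widths, each = spec$sites_per_tf),
                              spec$min_gap, spec$cluster_span)
      if (is.null(plan)) next
      tf_of <- rep(seq_along(pwms), each = spec$sites_per_tf)
      strands <- sample(c("+", "-"), n_sites, replace = TRUE)
      for (k in seq_len(n_sites)) {
        cons <- pwm_consensus(pwms[[tf_of[k]]])
        ins <- if (strands[k] == "+") cons else revcomp(cons)
        idx <- plan[k] + seq_len(nchar(ins))  # plan is 0-based start
        seqv[idx] <- strsplit(ins, "", fixed = TRUE)[[1L]]
      }
      seq1 <- paste(seqv, collapse = "")
      found <- lapply(pwms, scan_crm, seq = seq1, t = spec$scan_threshold)
      n_found <- sum(vapply(found, nrow, integer(1)))
      exact <- n_found == n_sites &&
        all(vapply(seq_along(pwms), function(ti) {
          f <- found[[ti]]
          planted <- sort(plan[tf_of == ti])
          nrow(f) == length(planted) && all(sort(f$start) == planted)
        }, logical(1)))
      if (exact) break
    }
    crms[ci] <- seq1
    site_frames[[ci]] <- {
      df <- tfbs_frame(tf = names(spec$tf_specs)[tf_of], start = plan,
                       strand = strands, width = rep(widths, each = spec$sites_per_tf),
                       score = vapply(pwms, function(p) p$s_max, numeric(1))[tf_of],
                       q = rep(1, n_sites))
      df <- df[order(df$start), , drop = FALSE]
      rownames(df) <- NULL
      df
    }
  }
  list(crms = sequence_set(ids, crms, alphabet = "dna"),
       sites = structure(stats::setNames(site_frames, ids), class = "tfbs_map"))
}

# 0-based start positions for a compact site cluster: sites in random
# order, random gaps of at least `gap` bp, total span at most `span` bp,
# random offset within the CRM; NULL when the draw fails.
plant_positions <- function(len, widths, gap, span) {
  n <- length(widths)
  ord <- sample.int(n)   # random left-to-right site order
  max_extra <- span - sum(widths) - (n - 1L) * gap
  if (max_extra < 0) return(NULL)
  extra <- if (n > 1L) stats::rmultinom(1L, sample.int(max_extra + 1L, 1L) - 1L,
                                        rep(1, n - 1L))[, 1L] else integer(0)
  gaps <- rep(gap, max(n - 1L, 0L)) + extra
  rel <- cumsum(c(0L, widths[ord][-n] + gaps))
  total <- rel[n] + widths[ord][n]
  offset <- sample.int(len - total + 1L, 1L) - 1L
  starts <- integer(n)
  starts[ord] <- as.integer(offset + rel)
  starts
}

spec_roles_per_crm <- function(spec) {
  panel <- spec_panel(spec)
  ids <- sprintf("crm%02d", seq_len(spec$n_crms))
  stats::setNames(lapply(seq_len(spec$n_crms), function(ci) {
    r <- panel$literature_roles
    if (!is.null(spec$dual_tf) && ci %in% spec$dual_act_crms)
      r[spec$dual_tf] <- 1
    r
  }), ids)
}

#' Generate observed expression profiles
#'
#' Forward-predicts each CRM from the planted sites, ground-truth
#' parameters and planted per-CRM roles, then adds Gaussian noise of SD
#' `noise_sd`, clipped at 0.
#'
#' @param sites planted `tfbs_map` from [make_crm_sequences()].
#' @param concentrations [make_concentration_profiles()] output.
#' @param spec a [generator_spec()].
#' @return a [profile_set()] with one track per CRM.
#' @export
make_expression <- function(sites, concentrations, spec) {
  set.seed(derive_seed(spec$seed, 2))
  roles <- spec_roles_per_crm(spec)
  tracks <- lapply(names(sites), function(id) {
    pred <- predict_expression(sites[[id]], concentrations, spec$params,
                               roles[[id]])
    v <- as.numeric(pred$profiles[1L, ])
    if (spec$noise_sd > 0)
      v <- pmax(v + stats::rnorm(length(v), 0, spec$noise_sd), 0)
    v
  })
  profile_set(concentrations$axis, stats::setNames(tracks, names(sites)))
}

#' Generate a complete synthetic dataset
#'
#' Runs the whole generator: gradients, CRM sequences with planted sites,
#' PWMs, observed expression, the ground-truth role labels (`"s"` for the
#' planted dual TF, `"+"`/`"-"` otherwise), and protein sequences whose
#' SUMO-consensus content matches those labels.  Byte-reproducible given
#' the spec's seed.
#'
#' @param spec a [generator_spec()].
#' @return an object of class `synthetic_dataset`: list with `crms`,
#'   `pwms`, `concentrations`, `observed`, `proteins`, `panel` and `truth`
#'   (spec echo, ground-truth params, planted `sites`, per-CRM roles and
#'   per-TF `role_labels`).
#' @export
make_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  conc <- make_concentration_profiles(spec)
  sq <- make_crm_sequences(spec)
  obs <- make_expression(sq$sites, conc, spec)
  panel <- spec_panel(spec)
  labels <- ifelse(panel$literature_roles > 0, "+", "-")
  if (!is.null(spec$dual_tf)) labels[spec$dual_tf] <- "s"
  proteins <- make_protein_set(stats::setNames(labels, panel$names),
                               seed = derive_seed(spec$seed, 3))
  structure(list(crms = sq$crms, pwms = spec_pwms(spec),
                 concentrations = conc, observed = obs, proteins = proteins,
                 panel = panel,
                 truth = list(spec = spec, params = spec$params,
                              sites = sq$sites,
                              roles_per_crm = spec_roles_per_crm(spec),
                              role_labels = stats::setNames(labels, panel$names))),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d CRMs x %d TFs, %d AP positions, dual TF: %s\n",
              length(x$crms), length(x$panel$names),
              length(x$concentrations$axis),
              if (is.null(x$truth$spec$dual_tf)) "none" else x$truth$spec$dual_tf))
  invisible(x)
}

#' Assemble a training dataset from a synthetic dataset
#'
#' @param x a [make_synthetic_dataset()] result.
#' @param rescan if `TRUE` (default) the TFBS-map is rebuilt by scanning
#'   the sequences — the same route real data takes; otherwise the planted
#'   truth map is used directly.
#' @param t scan threshold in bits (defaults to the spec's).
#' @return a [crm_dataset()].
#' @export
as_crm_dataset <- function(x, rescan = TRUE, t = NULL) {
  stopifnot(inherits(x, "synthetic_dataset"))
  if (is.null(t)) t <- x$truth$spec$scan_threshold
  sites <- if (rescan) build_tfbs_map(x$crms, x$pwms, t = t, warn = FALSE)
  else x$truth$sites
  crm_dataset(x$crms, sites, x$concentrations, x$observed, x$panel)
}

#' Generate TF protein sequences with controlled SUMO-motif content
#'
#' Random amino-acid sequences; TFs labelled `"s"` (dual) receive
#' `n_planted` planted SUMOylation consensus instances (Psi-K-x-E) while
#' single-role TFs are rejection-sampled to contain none.  Planted and
#' verified against [scan_consensus()], so generator truth and scanner
#' agree exactly.
#'
#' @param role_labels named character vector over TFs with values `"+"`,
#'   `"-"` or `"s"`.
#' @param seed integer seed.
#' @param length protein length in residues.
#' @param n_planted SUMO motifs planted per dual TF.
#' @return a protein [sequence_set()].
#' @export
make_protein_set <- function(role_labels, seed = 1, length = 200,
                             n_planted = 1) {
  set.seed(seed)
  aa <- strsplit(AA_ALPHABET, "", fixed = TRUE)[[1L]]
  pat <- sumo_pattern()
  draw_clean <- function() {
    repeat {
      s <- paste(sample(aa, length, replace = TRUE), collapse = "")
      if (nrow(scan_consensus(s, pat)) == 0L) return(s)
    }
  }
  seqs <- vapply(names(role_labels), function(tf) {
    if (role_labels[[tf]] != "s") return(draw_clean())
    repeat {
      s <- strsplit(draw_clean(), "", fixed = TRUE)[[1L]]
      w <- length(pat$positions)
      slots <- floor(seq(10, length(s) - w - 10, length.out = n_planted))
      for (k in seq_len(n_planted)) {
        inst <- vapply(pat$positions, function(set) sample(set, 1L), character(1))
        s[slots[k] + seq_len(w)] <- inst
      }
      s <- paste(s, collapse = "")
      if (nrow(scan_consensus(s, pat)) == n_planted) return(s)
    }
  }, character(1))
  sequence_set(names(role_labels), seqs, alphabet = "protein")
}
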
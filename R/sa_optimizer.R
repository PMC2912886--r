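#' CRM training datasets
#'
#' Bundles everything a fit needs: CRM sequences, their TFBS-map, the TF
#' concentration tracks, the observed per-CRM expression profiles and the
#' TF panel.  Concentration tracks must cover every panel TF and observed
#' tracks every CRM, all on a common AP axis.
#'
#' @param crms a [sequence_set()] of CRM DNA sequences.
#' @param sites a [build_tfbs_map()] result over the same CRMs.
#' @param concentrations a [profile_set()] with one track per panel TF.
#' @param observed a [profile_set()] with one track per CRM.
#' @param panel a [tf_panel()].
#' @return an object of class `crm_dataset`.
#' @export
crm_dataset <- function(crms, sites, concentrations, observed, panel) {
  stopifnot(inherits(crms, "sequence_set"), inherits(sites, "tfbs_map"),
            inherits(concentrations, "profile_set"),
            inherits(observed, "profile_set"), inherits(panel, "tf_panel"))
  if (!identical(names(crms), names(sites)))
    stop("sites must cover exactly the CRMs, in order")
  miss <- setdiff(panel$names, rownames(concentrations$profiles))
  if (length(miss))
    stop("missing concentration track(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(names(crms), rownames(observed$profiles))
  if (length(miss))
    stop("missing observed profile(s): ", paste(miss, collapse = ", "))
  if (!isTRUE(all.equal(concentrations$axis, observed$axis)))
    stop("concentration and observed profiles are on different AP axes")
  structure(list(crms = crms, sites = sites, concentrations = concentrations,
                 observed = observed, panel = panel),
            class = "crm_dataset")
}

#' @export
print.crm_dataset <- function(x, ...) {
  cat(sprintf("crm_dataset: %d CRMs, %d TFs, %d AP positions\n",
              length(x$crms), length(x$panel$names),
              length(x$concentrations$axis)))
  invisible(x)
}

#' Per-CRM role assignments
#'
#' Expands a single configuration (or per-CRM configurations) into the
#' named list of +1/-1 role vectors, one per CRM, used by the objective.
#'
#' @param dataset a [crm_dataset()].
#' @param config a configuration index, a +1/-1 role vector over the
#'   panel, or a named list of either (one per CRM).
#' @return named list of named +1/-1 vectors, one per CRM.
#' @export
roles_per_crm <- function(dataset, config) {
  tfs <- dataset$panel$names
  one <- function(cfg) {
    if (length(cfg) == length(tfs) && all(cfg %in% c(-1, 1))) {
      r <- as.numeric(cfg)
      if (!is.null(names(cfg))) {
        if (!setequal(names(cfg), tfs)) stop("role vector names must match panel")
        r <- as.numeric(cfg[tfs])
      }
    } else if (length(cfg) == 1L && is.numeric(cfg)) {
      r <- roles_from_index(cfg, length(tfs))
    } else stop("configuration must be an index or a +1/-1 role vector")
    stats::setNames(r, tfs)
  }
  ids <- names(dataset$crms)
  if (is.list(config)) {
    if (!all(ids %in% names(config)))
      stop("per-CRM config list must cover every CRM")
    stats::setNames(lapply(ids, function(id) one(config[[id]])), ids)
  } else {
    stats::setNames(rep(list(one(config)), length(ids)), ids)
  }
}

# Static per-CRM structures for the C++ objective.
dataset_structs <- function(dataset, roles) {
  ids <- names(dataset$crms)
  stats::setNames(lapply(ids, function(id) {
    cs <- crm_struct(dataset$sites[[id]], dataset$concentrations,
                     dataset$panel$names, roles[[id]])
    cs$obs <- as.numeric(dataset$observed$profiles[id, ])
    cs
  }), ids)
}

#' Mean-CC fitting objective
#'
#' The quantity simulated annealing maximizes: the arithmetic mean over
#' the dataset's CRMs of the Pearson correlation between the observed
#' profile and the model prediction under `params`.
#'
#' @param params a [model_params()].
#' @param dataset a [crm_dataset()].
#' @param config per-CRM roles as accepted by [roles_per_crm()].
#' @return mean CC over CRMs.
#' @export
objective <- function(params, dataset, config) {
  roles <- roles_per_crm(dataset, config)
  structs <- dataset_structs(dataset, roles)
  tfs <- dataset$panel$names
  cpp_objective(unname(structs), params$K[tfs], params$E_act[tfs],
                params$E_rep[tfs], params$G0, params$R0, params$d)
}

#' Simulated annealing schedules
#'
#' Geometric cooling: at iteration `k` the temperature is
#' `T0 * alpha^k`.  Defaults follow the analysis protocol (1000
#' iterations, best over 5 independent repeats); `T0` and `alpha` are
#' package choices made so acceptance decays smoothly over 1000 steps.
#'
#' @param T0 initial temperature (> 0).
#' @param alpha geometric cooling factor in `(0, 1)`.
#' @param iterations Metropolis steps per repeat.
#' @param repeats independent restarts; the best-ever fit is returned and
#'   per-repeat bests are averaged.
#' @param seed master seed; each repeat uses a derived sub-seed, so runs
#'   are exactly reproducible.
#' @param sigma proposal step size: SD of the log-normal multiplicative
#'   step for rate-like parameters and of the additive Gaussian step for
#'   `G0`.
#' @return an object of class `sa_schedule`.
#' @export
sa_schedule <- function(T0 = 0.1, alpha = 0.99, iterations = 1000,
                        repeats = 5, seed = 1, sigma = 0.5) {
  stopifnot(T0 > 0, alpha > 0, alpha < 1, iterations >= 0, repeats >= 1,
            sigma > 0)
  structure(list(T0 = T0, alpha = alpha, iterations = as.integer(iterations),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 sigma = sigma),
            class = "sa_schedule")
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1009 * as.numeric(k)) %% 2147483647)
}

#' Default parameter bounds for fitting
#'
#' Rate-like parameters (`K`, `E_act`, `E_rep`, `R0`) are explored on a
#' log scale within their bounds; `G0` additively.  `E_rep` is capped at 1
#' so the quench factor stays a fraction.
#'
#' @return a named list of `c(lower, upper)` bounds per parameter type.
#' @export
default_bounds <- function() {
  list(K = c(0.01, 100), E_act = c(0.01, 20), E_rep = c(0.01, 1),
       G0 = c(-10, 10), R0 = c(0.01, 10))
}

# Free-parameter layout for a fit: K per TF; per TF either one E (the one
# matching its fixed role) or both (dual TFs / TFs whose role varies across
# CRMs); then G0 and R0.  d is fixed, not free.
param_layout <- function(panel, roles, dual_tfs, bounds) {
  tfs <- panel$names
  role_mat <- do.call(rbind, lapply(roles, function(r) r[tfs]))
  varies <- apply(role_mat, 2L, function(col) length(unique(col)) > 1L)
  dual <- union(dual_tfs, tfs[varies])
  rows <- list()
  add <- function(type, tf, log_scale) {
    b <- bounds[[type]]
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, tf = if (is.null(tf)) NA_character_ else tf,
      lower = b[1L], upper = b[2L], log_scale = log_scale,
      stringsAsFactors = FALSE)
  }
  for (tf in tfs) add("K", tf, TRUE)
  for (tf in tfs) {
    if (tf %in% dual) {
      add("E_act", tf, TRUE); add("E_rep", tf, TRUE)
    } else if (role_mat[1L, tf] > 0) add("E_act", tf, TRUE)
    else add("E_rep", tf, TRUE)
  }
  add("G0", NULL, FALSE)
  add("R0", NULL, TRUE)
  layout <- do.call(rbind, rows)
  layout$name <- ifelse(is.na(layout$tf), layout$type,
                        paste(layout$type, layout$tf, sep = "_"))
  attr(layout, "dual_tfs") <- dual
  layout
}

layout_init <- function(layout) {
  v <- numeric(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    lo <- layout$lower[i]; hi <- layout$upper[i]
    v[i] <- if (lo == hi) lo
    else if (layout$log_scale[i]) exp(stats::runif(1, log(lo), log(hi)))
    else stats::runif(1, lo, hi)
  }
  v
}

reflect_into <- function(x, lo, hi) {
  if (lo == hi) return(lo)
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  if (y < 0) y <- y + 2 * w
  if (y <= w) lo + y else lo + 2 * w - y
}

vector_to_params <- function(v, layout, tfs, d) {
  K <- Ea <- Er <- stats::setNames(rep(0, length(tfs)), tfs)
  G0 <- 0; R0 <- 1
  for (i in seq_len(nrow(layout))) {
    switch(layout$type[i],
           K = { K[layout$tf[i]] <- v[i] },
           E_act = { Ea[layout$tf[i]] <- v[i] },
           E_rep = { Er[layout$tf[i]] <- v[i] },
           G0 = { G0 <- v[i] },
           R0 = { R0 <- v[i] })
  }
  K[K <= 0] <- .Machine$double.eps   # unused Ks stay inert but valid
  model_params(K, Ea, Er, G0 = G0, R0 = R0, d = d,
               dual_tfs = attr(layout, "dual_tfs"))
}

#' Fit model parameters by simulated annealing
#'
#' Maximizes the mean-CC [objective()] by Metropolis simulated annealing
#' with geometric cooling.  Proposals pick one free parameter uniformly at
#' random and perturb it — multiplicative log-normal for positive
#' rate-like parameters, additive Gaussian for `G0` (step size
#' `schedule$sigma`) —
#' reflecting at the bounds.  Each repeat restarts from an independent
#' (log-)uniform draw within the bounds; results are deterministic given
#' the schedule's seed.
#'
#' @param dataset a [crm_dataset()].
#' @param config per-CRM roles as accepted by [roles_per_crm()].
#' @param schedule an [sa_schedule()].
#' @param bounds parameter bounds, as [default_bounds()].
#' @param dual_tfs TFs fitted with split activator/repressor
#'   effectiveness even if their role does not vary across CRMs.
#' @param d quench distance in bp (fixed during the fit).
#' @return an object of class `fit_result`: list with `best_params`
#'   ([model_params()]), `best_cc`, `mean_cc` and `se_cc` (over per-repeat
#'   bests), `per_crm_cc`, `trace` (per-repeat best objective) and
#'   `layout`.
#' @export
sa_fit <- function(dataset, config, schedule = sa_schedule(),
                   bounds = default_bounds(), dual_tfs = character(0),
                   d = 100) {
  stopifnot(inherits(dataset, "crm_dataset"), inherits(schedule, "sa_schedule"))
  roles <- roles_per_crm(dataset, config)
  structs <- unname(dataset_structs(dataset, roles))
  tfs <- dataset$panel$names
  layout <- param_layout(dataset$panel, roles, dual_tfs, bounds)
  nfree <- nrow(layout)
  eval_v <- function(v) {
    K <- Ea <- Er <- rep(0, length(tfs)); G0 <- 0; R0 <- 1
    for (i in seq_len(nfree)) {
      ty <- layout$type[i]; ti <- match(layout$tf[i], tfs)
      if (ty == "K") K[ti] <- v[i]
      else if (ty == "E_act") Ea[ti] <- v[i]
      else if (ty == "E_rep") Er[ti] <- v[i]
      else if (ty == "G0") G0 <- v[i]
      else R0 <- v[i]
    }
    K[K <= 0] <- .Machine$double.eps
    cpp_objective(structs, K, Ea, Er, G0, R0, d)
  }
  repeat_best <- numeric(schedule$repeats)
  best_v <- NULL; best_obj <- -Inf
  sigma <- if (is.null(schedule$sigma)) 0.5 else schedule$sigma
  for (r in seq_len(schedule$repeats)) {
    set.seed(derive_seed(schedule$seed, r))
    cur <- layout_init(layout)
    cur_obj <- eval_v(cur)
    rb_v <- cur; rb_obj <- cur_obj
    if (schedule$iterations > 0) {
      Tk <- schedule$T0
      for (k in seq_len(schedule$iterations)) {
        Tk <- Tk * schedule$alpha
        i <- sample.int(nfree, 1L)
        prop <- cur
        lo <- layout$lower[i]; hi <- layout$upper[i]
        prop[i] <- if (layout$log_scale[i]) {
          if (lo <= 0) lo  # degenerate zero bound: parameter pinned
          else exp(reflect_into(log(cur[i]) + stats::rnorm(1, 0, sigma),
                                log(lo), log(hi)))
        } else reflect_into(cur[i] + stats::rnorm(1, 0, sigma), lo, hi)
        pobj <- eval_v(prop)
        if (pobj >= cur_obj || stats::runif(1) < exp((pobj - cur_obj) / Tk)) {
          cur <- prop; cur_obj <- pobj
        }
        if (cur_obj > rb_obj) { rb_v <- cur; rb_obj <- cur_obj }
      }
    }
    repeat_best[r] <- rb_obj
    if (rb_obj > best_obj) { best_obj <- rb_obj; best_v <- rb_v }
  }
  best_params <- vector_to_params(best_v, layout, tfs, d)
  per_crm <- vapply(structs, function(cs)
    cpp_crm_cc(cs$site_tf, cs$site_center, cs$site_q, cs$site_role, cs$conc,
               cs$obs, best_params$K[tfs], best_params$E_act[tfs],
               best_params$E_rep[tfs], best_params$G0, best_params$R0, d),
    numeric(1))
  structure(list(best_params = best_params, best_cc = best_obj,
                 mean_cc = mean(repeat_best),
                 se_cc = if (schedule$repeats > 1)
                   stats::sd(repeat_best) / sqrt(schedule$repeats) else 0,
                 per_crm_cc = stats::setNames(per_crm, names(dataset$crms)),
                 trace = repeat_best, layout = layout),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: best CC %.4f, mean over %d repeat(s) %.4f (SE %.4f)\n",
              x$best_cc, length(x$trace), x$mean_cc, x$se_cc))
  invisible(x)
}
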
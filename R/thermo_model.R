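#' TF panels and role configurations
#'
#' A `tf_panel` fixes the TF order and the published ("literature") role of
#' each TF; a configuration assigns every TF in the panel a role, +1 for
#' activator and -1 for repressor, and is encoded as an integer index in
#' `[0, 2^n)` with bit `i - 1` set iff TF `i` is an activator.
#'
#' @param names ordered character vector of unique TF ids.
#' @param literature_roles numeric vector of +1/-1, same length as `names`,
#'   or a character vector of `"+"`/`"-"`.
#' @return `tf_panel()`: an object of class `tf_panel` (list with `names`,
#'   `literature_roles`).
#' @export
tf_panel <- function(names, literature_roles) {
  if (anyDuplicated(names)) stop("TF names must be unique")
  if (is.character(literature_roles))
    literature_roles <- ifelse(literature_roles == "+", 1, -1)
  literature_roles <- as.numeric(literature_roles)
  if (length(literature_roles) != length(names) ||
      !all(literature_roles %in% c(-1, 1)))
    stop("literature_roles must be +1/-1, one per TF")
  structure(list(names = as.character(names),
                 literature_roles = stats::setNames(literature_roles, names)),
            class = "tf_panel")
}

#' The eight-TF gap-gene panel
#'
#' Bcd, Cad and TorRE as activators; Hb, Gt, Kni, Kr and Tll as repressors
#' — the published role assignment for the gap-gene network used as the
#' "literature configuration" baseline.
#'
#' @return a [tf_panel()] of 8 TFs.
#' @export
gap_gene_panel <- function() {
  tf_panel(c("Bcd", "Cad", "Hb", "Tll", "Gt", "Kr", "Kni", "TorRE"),
           c("+",   "+",   "-",  "-",   "-",  "-",  "-",   "+"))
}

#' @export
print.tf_panel <- function(x, ...) {
  cat(sprintf("tf_panel: %d TFs (%s)\n", length(x$names),
              paste(sprintf("%s%s", x$names,
                            ifelse(x$literature_roles > 0, "+", "-")),
                    collapse = " ")))
  invisible(x)
}

#' @rdname tf_panel
#' @param index configuration index in `[0, 2^n)`.
#' @param n number of TFs.
#' @return `roles_from_index()`: a +1/-1 vector of length `n`;
#'   `index_from_roles()`: an integer index.
#' @export
roles_from_index <- function(index, n) {
  stopifnot(index >= 0, index < 2^n)
  ifelse(bitwAnd(index, bitwShiftL(1L, seq_len(n) - 1L)) > 0, 1, -1)
}

#' @rdname tf_panel
#' @param roles a +1/-1 vector.
#' @export
index_from_roles <- function(roles) {
  sum(bitwShiftL(1L, which(roles > 0) - 1L))
}

#' Thermodynamic model parameters
#'
#' Parameters of the Reinitz-style expression model: a maximum association
#' constant `K` and an effectiveness `E` per TF, a dimensionless activation
#' threshold `G0` (the Gibbs free-energy threshold of transcription), the
#' maximal transcription rate `R0`, and the quench distance `d` in base
#' pairs within which an occupied repressor site reduces activator
#' contributions.  For a TF declared dual-functioning, activator and
#' repressor effectiveness (`E_act`, `E_rep`) are separate free parameters;
#' otherwise only the effectiveness matching the TF's configured role is
#' free.
#'
#' @param K named per-TF association constants (> 0).
#' @param E_act named per-TF activator effectiveness (>= 0).
#' @param E_rep named per-TF repressor effectiveness (in `[0, 1]`, so that
#'   the quench factor `1 - E_rep * f` stays in `[0, 1]`).
#' @param G0 activation threshold (dimensionless).
#' @param R0 maximal transcription rate (> 0).
#' @param d quench distance, base pairs (>= 0); not a free parameter.
#' @param dual_tfs character vector of TFs whose role may vary per CRM.
#' @return an object of class `model_params`.
#' @export
model_params <- function(K, E_act, E_rep, G0 = 0, R0 = 1, d = 100,
                         dual_tfs = character(0)) {
  tfs <- names(K)
  if (is.null(tfs)) stop("K must be a named vector (one entry per TF)")
  E_act <- E_act[tfs]; E_rep <- E_rep[tfs]
  if (anyNA(E_act) || anyNA(E_rep))
    stop("E_act and E_rep must cover every TF named in K")
  if (any(K <= 0)) stop("K must be > 0")
  if (any(E_act < 0)) stop("E_act must be >= 0")
  if (any(E_rep < 0 | E_rep > 1)) stop("E_rep must lie in [0, 1]")
  if (R0 <= 0) stop("R0 must be > 0")
  if (d < 0) stop("d must be >= 0")
  if (!all(dual_tfs %in% tfs))
    stop("dual_tfs must be a subset of the panel TFs")
  structure(list(K = K, E_act = E_act, E_rep = E_rep, G0 = G0, R0 = R0,
                 d = d, dual_tfs = dual_tfs),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params: %d TFs, G0 = %.3g, R0 = %.3g, d = %g bp%s\n",
              length(x$K), x$G0, x$R0, x$d,
              if (length(x$dual_tfs))
                paste0(", dual: ", paste(x$dual_tfs, collapse = ","))
              else ""))
  invisible(x)
}

#' Fractional occupancy of a single site
#'
#' Single-site thermodynamic binding isotherm: `f = Kvq / (1 + Kvq)` for
#' normalized affinity `q`, TF concentration `v` and association constant
#' `K`.  Monotone increasing in each argument, in `[0, 1)`.
#'
#' @param q normalized site affinity in `(0, 1]`.
#' @param v TF concentration (>= 0).
#' @param K association constant (> 0).
#' @return occupancy fraction.
#' @export
site_occupancy <- function(q, v, K) {
  if (any(q <= 0) || any(q > 1)) stop("q must lie in (0, 1]")
  if (any(v < 0)) stop("v must be >= 0")
  if (any(K <= 0)) stop("K must be > 0")
  x <- K * v * q
  x / (1 + x)
}

site_roles_for <- function(sites, roles) {
  r <- roles[sites$tf]
  if (anyNA(r))
    stop("site for TF absent from configuration: ",
         paste(unique(sites$tf[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Total activation score at one AP position
#'
#' Sum over activator sites of effectiveness times occupancy, each term
#' multiplied by `(1 - E_rep * f_j)` for every occupied repressor site `j`
#' whose center lies within `d` base pairs of the activator site's center
#' (short-range quenching).
#'
#' @param sites a `tfbs` data frame (one CRM's sites).
#' @param conc_at_x named per-TF concentrations at one AP position.
#' @param params a [model_params()].
#' @param roles named +1/-1 role vector applying to this CRM.
#' @return the activation score (>= 0).
#' @export
total_activation <- function(sites, conc_at_x, params, roles) {
  if (!nrow(sites)) return(0)
  role <- site_roles_for(sites, roles)
  f <- site_occupancy(sites$q, unname(conc_at_x[sites$tf]),
                      unname(params$K[sites$tf]))
  center <- sites$start + sites$width / 2
  act <- which(role > 0)
  rep_ <- which(role < 0)
  total <- 0
  for (i in act) {
    term <- params$E_act[[sites$tf[i]]] * f[i]
    for (j in rep_) {
      if (abs(center[i] - center[j]) <= params$d)
        term <- term * (1 - params$E_rep[[sites$tf[j]]] * f[j])
    }
    total <- total + term
  }
  total
}

#' Predict a CRM's expression profile
#'
#' Forward model: at each AP position the activation score is passed
#' through a logistic transcription gate,
#' `R(x) = R0 / (1 + exp(-(Sigma(x) - G0)))`, giving a rate in `(0, R0)`.
#' A CRM with no sites yields the flat basal rate `R0 / (1 + exp(G0))`.
#'
#' @param crm_sites a `tfbs` data frame (one CRM's sites).
#' @param concentrations a [profile_set()] with one track per TF.
#' @param params a [model_params()].
#' @param roles named +1/-1 role vector for this CRM.
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference
#'   implementation, used to cross-check the compiled path).
#' @return a [profile_set()] with a single track `"predicted"`.
#' @export
predict_expression <- function(crm_sites, concentrations, params, roles,
                               engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(concentrations, "profile_set"))
  tf_used <- unique(crm_sites$tf)
  missing <- setdiff(tf_used, rownames(concentrations$profiles))
  if (length(missing))
    stop("no concentration track for TF(s): ", paste(missing, collapse = ", "))
  vals <- if (engine == "cpp") {
    cs <- crm_struct(crm_sites, concentrations, names(roles), roles)
    cpp_predict_profile(cs$site_tf, cs$site_center, cs$site_q, cs$site_role,
                        cs$conc, params$K[names(roles)],
                        params$E_act[names(roles)], params$E_rep[names(roles)],
                        params$G0, params$R0, params$d)
  } else {
    vapply(seq_along(concentrations$axis), function(xi) {
      conc_at_x <- concentrations$profiles[, xi]
      s <- total_activation(crm_sites, conc_at_x, params, roles)
      params$R0 / (1 + exp(-(s - params$G0)))
    }, numeric(1))
  }
  profile_set(concentrations$axis, list(predicted = vals))
}

# Flattened per-CRM static arrays consumed by the C++ objective.
crm_struct <- function(sites, concentrations, tf_names, roles) {
  tf_idx <- match(sites$tf, tf_names)
  if (anyNA(tf_idx))
    stop("site TF not in panel: ", paste(unique(sites$tf[is.na(tf_idx)]),
                                         collapse = ", "))
  list(site_tf = as.integer(tf_idx),
       site_center = sites$start + sites$width / 2,
       site_q = sites$q,
       site_role = as.integer(site_roles_for(sites, roles)),
       conc = concentrations$profiles[tf_names, , drop = FALSE])
}

#' Pearson correlation between observed and predicted profiles
#'
#' The model's goodness-of-fit statistic.  If either profile has zero
#' variance the correlation is defined as 0 (a constant prediction carries
#' no shape information) and a warning is raised.
#'
#' @param observed,predicted [profile_set()] objects with identical axes
#'   and a single track each, or plain numeric vectors of equal length.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_cc <- function(observed, predicted) {
  v1 <- profile_values(observed)
  v2 <- profile_values(predicted)
  if (inherits(observed, "profile_set") && inherits(predicted, "profile_set") &&
      !isTRUE(all.equal(observed$axis, predicted$axis)))
    stop("observed and predicted profiles are on different axes")
  if (length(v1) != length(v2)) stop("profiles differ in length")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("zero-variance profile; CC defined as 0")
    return(0)
  }
  stats::cor(v1, v2)
}

profile_values <- function(x) {
  if (inherits(x, "profile_set")) {
    if (nrow(x$profiles) != 1L)
      stop("expected a single-track profile_set")
    as.numeric(x$profiles[1L, ])
  } else as.numeric(x)
}

#' Count free parameters of a model variant
#'
#' The Reinitz-style model has `2n + 2` free parameters for `n` TFs (one
#' `K` and one `E` per TF, plus `G0` and `R0`), plus one extra
#' effectiveness parameter per dual-functioning TF.  The Segal model's
#' count is `3n + 3|W| + |C|`, where `|W|` is the summed PWM width and
#' `|C|` the number of CRMs (only the count is implemented; the model
#' itself is out of scope).
#'
#' @param model `"reinitz"` or `"segal"`.
#' @param n number of TFs.
#' @param dual_tfs TFs allowed dual function (reinitz only).
#' @param pwm_total_width `|W|`, required for `"segal"`.
#' @param n_crms `|C|`, required for `"segal"`.
#' @return integer parameter count.
#' @export
count_free_parameters <- function(model = c("reinitz", "segal"), n,
                                  dual_tfs = character(0),
                                  pwm_total_width = NULL, n_crms = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 1)
  if (model == "reinitz")
    return(as.integer(2 * n + 2 + length(unique(dual_tfs))))
  if (is.null(pwm_total_width) || is.null(n_crms))
    stop("segal count requires pwm_total_width and n_crms")
  as.integer(3 * n + 3 * pwm_total_width + n_crms)
}
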
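#' Derive per-CRM roles for dual-function TFs
#'
#' For each declared dual TF, takes its per-CRM role from the SENSITIVITY
#' method's calls; CRMs where the method assigned no role (`NA`) fall back
#' to the TF's literature role.  All other TFs keep their literature roles
#' everywhere.
#'
#' @param sens a [sensitivity()] `method_result` covering all CRMs.
#' @param dual_tfs character vector of TFs allowed dual function.
#' @param panel a [tf_panel()].
#' @return an object of class `dual_assignment`: list with `dual_tfs`,
#'   `per_crm_roles` (data frame crm x dual TF roles) and
#'   `per_crm_config` (named list of full +1/-1 role vectors).
#' @export
assign_dual_roles <- function(sens, dual_tfs, panel) {
  stopifnot(inherits(sens, "method_result"), inherits(panel, "tf_panel"))
  if (!all(dual_tfs %in% panel$names))
    stop("dual TF(s) absent from panel: ",
         paste(setdiff(dual_tfs, panel$names), collapse = ", "))
  crms <- unique(sens$calls$crm)
  lit <- panel$literature_roles
  per_crm_config <- stats::setNames(lapply(crms, function(crm) {
    roles <- lit
    for (tf in dual_tfs) {
      call <- sens$calls[sens$calls$crm == crm & sens$calls$tf == tf, ]
      if (nrow(call) != 1L) stop("sensitivity result misses call for ",
                                 crm, " / ", tf)
      if (!is.na(call$role)) roles[tf] <- if (call$role == "ACT") 1 else -1
    }
    roles
  }), crms)
  per_crm_roles <- do.call(rbind, lapply(crms, function(crm) {
    r <- per_crm_config[[crm]][dual_tfs]
    data.frame(crm = crm, t(ifelse(r > 0, "ACT", "REP")),
               stringsAsFactors = FALSE, row.names = NULL,
               check.names = FALSE)
  }))
  structure(list(dual_tfs = dual_tfs, per_crm_roles = per_crm_roles,
                 per_crm_config = per_crm_config),
            class = "dual_assignment")
}

#' @export
print.dual_assignment <- function(x, ...) {
  nconf <- length(unique(vapply(x$per_crm_config, index_from_roles, numeric(1))))
  cat(sprintf("dual_assignment: dual TF(s) %s, %d distinct configuration(s)\n",
              paste(x$dual_tfs, collapse = ","), nconf))
  invisible(x)
}

#' Run the dual-function model-comparison experiment
#'
#' Trains, with an identical annealing schedule and master seed for every
#' variant, one simultaneous model per variant: the baseline (every TF in
#' its literature role for every CRM) plus one variant per requested dual
#' TF subset.  In a dual variant the named TFs take their
#' SENSITIVITY-derived role per CRM and are fitted with split
#' `E_activator` / `E_repressor` effectiveness, adding one free parameter
#' per dual TF to the baseline's `2n + 2`.
#'
#' @param dataset a [crm_dataset()].
#' @param sens a [sensitivity()] result on this dataset's CC matrix.
#' @param dual_variants list of character vectors, one per dual variant
#'   (e.g. `list("Hb", "Kr", c("Hb", "Kr"))`); the baseline is always run
#'   first.
#' @param schedule an [sa_schedule()].
#' @param bounds fit bounds.
#' @param d quench distance in bp.
#' @return an object of class `variant_report`: list with `table` (data
#'   frame: `variant`, `n_configs`, `n_params`, `mean_cc`, `se_cc`,
#'   `best_cc`), `fits` (named list of [sa_fit()] results) and
#'   `per_crm_cc` (CRMs x variants matrix at each variant's best fit).
#' @export
run_dual_experiment <- function(dataset, sens, dual_variants,
                                schedule = sa_schedule(),
                                bounds = default_bounds(), d = 100) {
  stopifnot(inherits(dataset, "crm_dataset"))
  panel <- dataset$panel
  n <- length(panel$names)
  variants <- c(list(character(0)), dual_variants)
  names(variants) <- vapply(variants, function(v) {
    if (!length(v)) "baseline" else paste0(paste(v, collapse = ""), "Dual")
  }, character(1))
  fits <- list(); rows <- list()
  for (vn in names(variants)) {
    dual <- variants[[vn]]
    config <- if (!length(dual)) panel$literature_roles
    else assign_dual_roles(sens, dual, panel)$per_crm_config
    fit <- sa_fit(dataset, config, schedule, bounds, dual_tfs = dual, d = d)
    fits[[vn]] <- fit
    nconf <- if (!length(dual)) 1L
    else length(unique(vapply(config, index_from_roles, numeric(1))))
    rows[[vn]] <- data.frame(
      variant = vn, n_configs = nconf,
      n_params = count_free_parameters("reinitz", n, dual),
      mean_cc = fit$mean_cc, se_cc = fit$se_cc, best_cc = fit$best_cc,
      stringsAsFactors = FALSE)
  }
  per_crm <- do.call(cbind, lapply(fits, function(f) f$per_crm_cc))
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 fits = fits, per_crm_cc = per_crm),
            class = "variant_report")
}

#' @export
print.variant_report <- function(x, ...) {
  cat("variant_report:\n")
  print.data.frame(x$table, digits = 4)
  invisible(x)
}

#' Write a variant report as TSV
#'
#' @param x a `variant_report`.
#' @param path output TSV path.
#' @param comment optional comment line(s).
#' @export
write_variant_report <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines("variant\tn_configs\tn_params\tmean_cc\tse_cc\tbest_cc", con)
  t <- x$table
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", t$variant, t$n_configs,
                     t$n_params, format_num(t$mean_cc), format_num(t$se_cc),
                     format_num(t$best_cc)), con)
  invisible(path)
}
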
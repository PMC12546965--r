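# Registry of model parameters ------------------------------------------------
#
# Every numeric input of the two cohort models lives here: base-case value,
# triangular Monte Carlo range, role (probability / cost / utility /
# structural) and time basis. Names carry an explicit time-basis suffix
# (_annual, _2wk, _4wk, _dose) because the models mix annual probabilities
# with per-course and per-dose costs; the suffix is the unit.
#
# The same clinical quantity can appear in both models with different Monte
# Carlo ranges (e.g. ciprofloxacin response), so registry rows are keyed by
# (name, model_scope) and `load_defaults()` resolves model-specific rows over
# shared ones.

.registry_df <- function() {
  spec <- function(name, role, base, lo, hi, basis, scope, source) {
    data.frame(name = name, role = role, base = base, mc_min = lo, mc_max = hi,
               time_basis = basis, model_scope = scope, source = source,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # -- primary prevention model -------------------------------------------
    spec("p_first_pouchitis_ppx_annual",    "probability", 0.10, 0.05, 0.25, "annual",     "primary",  "primary prevention RCT"),
    spec("p_first_pouchitis_no_ppx_annual", "probability", 0.40, 0.25, 0.50, "annual",     "primary",  "primary prevention RCT"),
    spec("p_recurrent_pouchitis_annual",    "probability", 0.39, 0.20, 0.50, "annual",     "primary",  "observational cohort"),
    spec("p_resp_cipro",                    "probability", 0.77, 0.60, 0.95, "per_course", "primary",  "clinical guideline estimate"),
    spec("p_resp_metro",                    "probability", 0.70, 0.55, 0.90, "per_course", "primary",  "clinical guideline estimate"),
    spec("p_resp_dual",                     "probability", 1.00, 1.00, 1.00, "per_course", "primary",  "structural assumption: terminal response"),
    spec("cost_probiotic_2wk",              "cost",        87.2,   50,  150, "per_cycle",  "primary",  "manufacturer US price"),
    spec("cost_cipro_2wk",                  "cost",          12,    6,   24, "per_course", "primary",  "Medicare drug cost"),
    spec("cost_metro_2wk",                  "cost",       22.68,   11,   45, "per_course", "primary",  "Medicare drug cost"),
    spec("cost_dual_4wk",                   "cost",         270,  140,  500, "per_course", "primary",  "Medicare drug cost"),
    spec("cost_first_episode_workup",       "cost",       612.6,  300, 1000, "per_course", "primary",  "Medicare fee schedule"),
    # -- secondary prevention (relapse) model -------------------------------
    spec("p_relapse_ppx_annual",            "probability", 0.14, 0.10, 0.50, "annual",     "secondary", "meta-analysis of RCTs"),
    spec("p_relapse_no_ppx_annual",         "probability", 0.39, 0.25, 0.55, "annual",     "secondary", "claims database study"),
    spec("p_resp_cipro",                    "probability", 0.77, 0.50, 0.90, "per_course", "secondary", "clinical guideline estimate"),
    spec("p_resp_metro",                    "probability", 0.70, 0.50, 0.90, "per_course", "secondary", "clinical guideline estimate"),
    spec("p_resp_dual",                     "probability", 0.69, 0.50, 0.90, "per_course", "secondary", "clinical guideline estimate"),
    spec("p_resp_vdz",                      "probability", 0.52, 0.30, 0.70, "per_course", "secondary", "clinical guideline estimate"),
    spec("p_resp_ifx",                      "probability", 1.00, 1.00, 1.00, "per_course", "secondary", "structural assumption: terminal response"),
    spec("p_lor_vdz_annual",                "probability", 0.40, 0.20, 0.60, "annual",     "secondary", "published literature"),
    spec("cost_probiotic_4wk",              "cost",         174,  100,  300, "per_cycle",  "secondary", "manufacturer US price"),
    spec("cost_cipro_4wk",                  "cost",          24,   12,   48, "per_course", "secondary", "Medicare drug cost"),
    spec("cost_metro_4wk",                  "cost",        45.4,   25,   80, "per_course", "secondary", "Medicare drug cost"),
    spec("cost_dual_4wk",                   "cost",         270,  150,  500, "per_course", "secondary", "Medicare drug cost"),
    spec("cost_vdz_dose",                   "cost",        6803, 3500, 10000, "per_dose",  "secondary", "Medicare Part B, per 300 mg"),
    spec("cost_ifx_dose",                   "cost",         987,  500, 1500, "per_dose",   "secondary", "Medicare Part B, per 300 mg"),
    spec("cost_carp_eval",                  "cost",       128.4,   70,  200, "per_course", "secondary", "Medicare fee schedule"),
    # -- shared --------------------------------------------------------------
    spec("utility_no_pouchitis",            "utility",     0.91, 0.70, 0.95, "annual",        "shared", "published utility literature"),
    spec("utility_active_pouchitis",        "utility",     0.46, 0.30, 0.60, "annual",        "shared", "published utility literature"),
    spec("ifx_weight_kg",                   "structural",    70,   70,   70, "dimensionless", "shared", "base-case adult male, 70 kg")
  ))
}

.model_scopes <- c("primary", "secondary", "primary_extended")

# Parameters borrowed from the secondary model when the primary model is
# extended with biologic therapy after dual-antibiotic failure.
.extended_borrow <- c("p_resp_dual", "p_resp_vdz", "p_resp_ifx", "p_lor_vdz_annual",
                      "cost_vdz_dose", "cost_ifx_dose")

#' Parameter registry
#'
#' Returns the typed registry of all model parameters: base-case value,
#' triangular Monte Carlo range (`mc_min`, mode = `base`, `mc_max`), role,
#' time basis and model scope. With `model` given, rows are resolved to the
#' view seen by that model: shared rows are included and, for
#' `"primary_extended"`, the biologic-pathway rows of the secondary model are
#' appended (dual-antibiotic response drops from the structural 1.0 to its
#' evidence-based value once the model continues past dual antibiotics).
#'
#' @param model `NULL` for the raw registry, or one of `"primary"`,
#'   `"secondary"`, `"primary_extended"`.
#' @return A `data.frame` with columns `name`, `role`, `base`, `mc_min`,
#'   `mc_max`, `time_basis`, `model_scope`, `source`.
#' @export
#' @examples
#' head(param_registry("primary"))
param_registry <- function(model = NULL) {
  reg <- .registry_df()
  if (is.null(model)) return(reg)
  model <- match.arg(model, .model_scopes)
  if (model == "primary_extended") {
    base <- reg[reg$model_scope %in% c("primary", "shared"), ]
    base <- base[base$name != "p_resp_dual", ]  # replaced by the 0.69 estimate
    extra <- reg[reg$model_scope == "secondary" & reg$name %in% .extended_borrow, ]
    out <- rbind(base, extra)
  } else {
    out <- reg[reg$model_scope %in% c(model, "shared"), ]
  }
  stopifnot(!anyDuplicated(out$name))
  rownames(out) <- NULL
  out
}

.registry_row <- function(name, model) {
  reg <- param_registry(model)
  i <- match(name, reg$name)
  if (is.na(i)) {
    stop(sprintf("unknown parameter '%s' for model scope '%s'", name, model),
         call. = FALSE)
  }
  reg[i, ]
}

#' Base-case parameter set
#'
#' Loads the full base-case parameter set for a model scope, exactly as
#' tabulated. Idempotent: repeated calls return identical value maps.
#'
#' @param model One of `"primary"`, `"secondary"`, `"primary_extended"`.
#' @return A `parameter_set`: list with `values` (named numeric), `model`,
#'   `provenance` and `seed_info`.
#' @export
#' @examples
#' ps <- load_defaults("primary")
#' ps$values[["p_first_pouchitis_no_ppx_annual"]]  # 0.4
load_defaults <- function(model = c("primary", "secondary", "primary_extended")) {
  model <- match.arg(model)
  reg <- param_registry(model)
  values <- stats::setNames(reg$base, reg$name)
  structure(list(values = values, model = model,
                 provenance = "base_case", seed_info = NULL),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set: %s, %d parameters, provenance=%s>\n",
              x$model, length(x$values), x$provenance))
  print(x$values)
  invisible(x)
}

.role_bounds_ok <- function(role, value) {
  switch(role,
         probability = ,
         utility = value >= 0 && value <= 1,
         cost = value >= 0,
         TRUE)
}

#' Override parameters in a set
#'
#' Returns a new parameter set differing from `ps` only at the named
#' parameters; the input is never mutated. Values must respect the
#' parameter's role bounds (probabilities and utilities in [0, 1], costs
#' non-negative) but may lie outside the Monte Carlo range: one-way
#' sensitivity sweeps deliberately go beyond it.
#'
#' @param ps A `parameter_set`.
#' @param name Parameter name(s).
#' @param value Replacement value(s), recycled against `name` if scalar.
#' @return A new `parameter_set` with `provenance = "override"`.
#' @export
#' @examples
#' base <- load_defaults("primary")
#' cheap <- override(base, "cost_probiotic_2wk", 41)
override <- function(ps, name, value) {
  stopifnot(inherits(ps, "parameter_set"))
  if (length(value) == 1L) value <- rep(value, length(name))
  stopifnot(length(name) == length(value))
  out <- ps
  for (i in seq_along(name)) {
    row <- .registry_row(name[i], ps$model)
    if (!.role_bounds_ok(row$role, value[i])) {
      stop(sprintf("value %g violates %s bounds for parameter '%s'",
                   value[i], row$role, name[i]), call. = FALSE)
    }
    out$values[[name[i]]] <- value[i]
  }
  out$provenance <- "override"
  out
}

#' Triangular inverse CDF used for Monte Carlo draws
#'
#' Quantile function of the triangular distribution with support
#' `[mc_min, mc_max]` and mode at the base-case value, the distribution
#' attached to every parameter with a Monte Carlo range. Degenerate specs
#' (`mc_min == mc_max`) return the point mass.
#'
#' @param spec A one-row slice of [param_registry()] (or any list with
#'   `mc_min`, `base`, `mc_max`).
#' @param u Probabilities in [0, 1]; vectorised.
#' @return Quantiles; monotone non-decreasing in `u`, with
#'   `sample_triangular(spec, 0) == mc_min` and
#'   `sample_triangular(spec, 1) == mc_max`.
#' @export
#' @examples
#' spec <- param_registry("primary")[1, ]
#' sample_triangular(spec, c(0, 0.5, 1))
sample_triangular <- function(spec, u) {
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]", call. = FALSE)
  qtri(u, spec$mc_min, spec$base, spec$mc_max)
}

# scalar parameters a <= c <= b; vectorised over u
qtri <- function(u, a, c, b) {
  stopifnot(a <= c, c <= b)
  if (b == a) return(rep(a, length(u)))
  fc <- (c - a) / (b - a)
  ifelse(u <= fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Validate a parameter set
#'
#' Checks completeness (every registry name for the model scope present) and
#' role bounds. Violations are returned as data, not raised.
#'
#' @param ps A `parameter_set`.
#' @param model Scope to validate against; defaults to the set's own scope.
#' @return A `data.frame` with columns `parameter` and `rule`; zero rows iff
#'   the set is valid.
#' @export
validate_parameters <- function(ps, model = ps$model) {
  reg <- param_registry(model)
  out <- data.frame(parameter = character(), rule = character(),
                    stringsAsFactors = FALSE)
  missing <- setdiff(reg$name, names(ps$values))
  for (m in missing) {
    out <- rbind(out, data.frame(parameter = m, rule = "missing"))
  }
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    if (!nm %in% names(ps$values)) next
    v <- ps$values[[nm]]
    if (!is.finite(v)) {
      out <- rbind(out, data.frame(parameter = nm, rule = "non-finite"))
    } else if (!.role_bounds_ok(reg$role[i], v)) {
      out <- rbind(out, data.frame(parameter = nm,
                                   rule = paste0(reg$role[i], "-bounds")))
    }
  }
  out
}

#' Export the registry to CSV
#'
#' @param path Output file.
#' @param model Optional scope filter, as in [param_registry()].
#' @return `path`, invisibly.
#' @export
export_registry_csv <- function(path, model = NULL) {
  utils::write.csv(param_registry(model), path, row.names = FALSE)
  invisible(path)
}
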
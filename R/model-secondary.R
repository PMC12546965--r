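# Secondary prevention model: patients with relapsing pouchitis enter in
# remission, in 4-week cycles. Relapses are treated empirically (no workup):
# ciprofloxacin -> metronidazole -> ciprofloxacin+tinidazole, each a one-cycle
# course; later relapses reuse the previously effective antibiotic and
# failures escalate. Dual-antibiotic failure defines chronic
# antibiotic-refractory pouchitis (CARP): a one-time evaluation, probiotic
# discontinuation, vedolizumab (with annual loss of response among
# responders), and infliximab as the absorbing terminal therapy.

#' Biologic dosing schedule
#'
#' Encodes an intravenous biologic's label schedule (doses at weeks 0, 2 and
#' 6, then every 8 weeks) on the model's cycle grid. Week-2 and week-6 doses
#' cannot sit exactly on a 4-week grid, so on that grid the entry cycle
#' carries one dose and the next cycle two, with maintenance every second
#' cycle thereafter; on a 2-week grid the doses fall on cycles 0, 1 and 3
#' with maintenance every fourth cycle. Infliximab (5 mg/kg at the 70 kg
#' base-case weight) is pro-rated linearly from the per-300 mg price.
#'
#' @param drug `"VDZ"` or `"IFX"`.
#' @param ps A `parameter_set` containing the dose cost (and, for IFX, the
#'   body weight).
#' @param cycle_length_weeks 4 (secondary model) or 2 (extended primary).
#' @return A `biologic_schedule`: list with `drug`, `induction_cycles`,
#'   `induction_doses`, `maintenance_interval_cycles`, `dose_cost_ref`,
#'   `dose_scale`.
#' @export
#' @examples
#' ps <- load_defaults("secondary")
#' biologic_schedule("IFX", ps)$dose_scale  # 350 mg / 300 mg
biologic_schedule <- function(drug = c("VDZ", "IFX"), ps,
                              cycle_length_weeks = 4) {
  drug <- match.arg(drug)
  stopifnot(cycle_length_weeks %in% c(2, 4))
  if (cycle_length_weeks == 4) {
    induction <- c(0L, 1L); doses <- c(1L, 2L); interval <- 2L
  } else {
    induction <- c(0L, 1L, 3L); doses <- c(1L, 1L, 1L); interval <- 4L
  }
  if (drug == "VDZ") {
    ref <- "cost_vdz_dose"; scale <- 1   # flat 300 mg dosing
  } else {
    ref <- "cost_ifx_dose"               # 5 mg/kg, priced per 300 mg
    scale <- ps$values[["ifx_weight_kg"]] * 5 / 300
  }
  structure(list(drug = drug, induction_cycles = induction,
                 induction_doses = doses,
                 maintenance_interval_cycles = interval,
                 dose_cost_ref = ref, dose_scale = scale),
            class = "biologic_schedule")
}

#' Biologic drug cost accrued in a cycle
#'
#' @param schedule A [biologic_schedule()].
#' @param cycles_since_start Cycles since the biologic was started (>= 0).
#' @param ps A `parameter_set` holding the per-dose cost.
#' @return Cost (USD) of the doses falling in that cycle; 0 off the dosing
#'   grid.
#' @export
biologic_cycle_cost <- function(schedule, cycles_since_start, ps) {
  stopifnot(inherits(schedule, "biologic_schedule"), cycles_since_start >= 0)
  per_dose <- ps$values[[schedule$dose_cost_ref]] * schedule$dose_scale
  i <- match(cycles_since_start, schedule$induction_cycles)
  if (!is.na(i)) return(schedule$induction_doses[i] * per_dose)
  last_ind <- max(schedule$induction_cycles)
  if (cycles_since_start > last_ind &&
      (cycles_since_start - last_ind) %% schedule$maintenance_interval_cycles == 0) {
    return(per_dose)
  }
  0
}

.secondary_states <- c("rem0", "cipro", "rem_cipro", "metro", "rem_metro",
                       "dual", "rem_dual", "vdz_i1", "vdz_i2", "vdz_m1",
                       "vdz_md", "ifx_0", "ifx_1", "ifx_m1", "ifx_md")

.build_secondary_arm <- function(arm = c("probiotic", "no_prophylaxis"),
                                 cl = 1 / 13) {
  arm <- match.arg(arm)
  ids <- .secondary_states
  S <- length(ids)
  p_rel_name <- if (arm == "probiotic") "p_relapse_ppx_annual" else
    "p_relapse_no_ppx_annual"
  pre_carp <- c("rem0", "cipro", "rem_cipro", "metro", "rem_metro", "dual",
                "rem_dual")
  active <- c("cipro", "metro", "dual", "vdz_i1", "vdz_i2")
  utility_ref <- stats::setNames(
    ifelse(ids %in% active, "utility_active_pouchitis", "utility_no_pouchitis"),
    ids)

  trans_fn <- function(cycle, ps) {
    p <- ps$values
    prel <- to_cycle_probability(p[[p_rel_name]], cl)
    lor <- to_cycle_probability(p[["p_lor_vdz_annual"]], cl)
    rc <- p[["p_resp_cipro"]]
    rm <- p[["p_resp_metro"]]
    rd <- p[["p_resp_dual"]]
    rv <- p[["p_resp_vdz"]]
    M <- matrix(0, S, S, dimnames = list(ids, ids))
    M["rem0", "cipro"] <- prel;      M["rem0", "rem0"] <- 1 - prel
    M["cipro", "rem_cipro"] <- rc;   M["cipro", "metro"] <- 1 - rc
    M["rem_cipro", "cipro"] <- prel; M["rem_cipro", "rem_cipro"] <- 1 - prel
    M["metro", "rem_metro"] <- rm;   M["metro", "dual"] <- 1 - rm
    M["rem_metro", "metro"] <- prel; M["rem_metro", "rem_metro"] <- 1 - prel
    M["dual", "rem_dual"] <- rd;     M["dual", "vdz_i1"] <- 1 - rd
    M["rem_dual", "dual"] <- prel;   M["rem_dual", "rem_dual"] <- 1 - prel
    M["vdz_i1", "vdz_i2"] <- 1
    M["vdz_i2", "vdz_m1"] <- rv;     M["vdz_i2", "ifx_0"] <- 1 - rv
    M["vdz_m1", "ifx_0"] <- lor;     M["vdz_m1", "vdz_md"] <- 1 - lor
    M["vdz_md", "ifx_0"] <- lor;     M["vdz_md", "vdz_m1"] <- 1 - lor
    M["ifx_0", "ifx_1"] <- 1
    M["ifx_1", "ifx_m1"] <- 1
    M["ifx_m1", "ifx_md"] <- 1
    M["ifx_md", "ifx_m1"] <- 1
    M
  }

  state_cost_fn <- function(ps) {
    cost <- stats::setNames(numeric(S), ids)
    if (arm == "probiotic") {
      # continued through relapses, discontinued at CARP
      cost[pre_carp] <- ps$values[["cost_probiotic_4wk"]]
    }
    vdz <- biologic_schedule("VDZ", ps, cycle_length_weeks = 4)
    ifx <- biologic_schedule("IFX", ps, cycle_length_weeks = 4)
    cost["vdz_i1"] <- biologic_cycle_cost(vdz, 0L, ps)
    cost["vdz_i2"] <- biologic_cycle_cost(vdz, 1L, ps)
    cost["vdz_md"] <- biologic_cycle_cost(vdz, 3L, ps)
    cost["ifx_0"] <- biologic_cycle_cost(ifx, 0L, ps)
    cost["ifx_1"] <- biologic_cycle_cost(ifx, 1L, ps)
    cost["ifx_md"] <- biologic_cycle_cost(ifx, 3L, ps)
    unname(cost)
  }

  entry_cost_fn <- function(ps) {
    p <- ps$values
    E <- matrix(0, S, S, dimnames = list(ids, ids))
    E["rem0", "cipro"] <- p[["cost_cipro_4wk"]]
    E["rem_cipro", "cipro"] <- p[["cost_cipro_4wk"]]
    E["cipro", "metro"] <- p[["cost_metro_4wk"]]
    E["rem_metro", "metro"] <- p[["cost_metro_4wk"]]
    E["metro", "dual"] <- p[["cost_dual_4wk"]]
    E["rem_dual", "dual"] <- p[["cost_dual_4wk"]]
    E["dual", "vdz_i1"] <- p[["cost_carp_eval"]]
    E
  }

  tags <- list(
    ever_relapse = setdiff(ids, "rem0"),
    ever_metro = setdiff(ids, c("rem0", "cipro", "rem_cipro")),
    ever_dual = c("dual", "rem_dual", "vdz_i1", "vdz_i2", "vdz_m1", "vdz_md",
                  "ifx_0", "ifx_1", "ifx_m1", "ifx_md"),
    ever_carp = c("vdz_i1", "vdz_i2", "vdz_m1", "vdz_md",
                  "ifx_0", "ifx_1", "ifx_m1", "ifx_md"),
    ever_ifx = c("ifx_0", "ifx_1", "ifx_m1", "ifx_md"))

  init <- c(1, numeric(S - 1L))
  new_strategy_model(name = paste0("secondary_", arm),
                     state_ids = ids, utility_ref = utility_ref,
                     state_cost_fn = state_cost_fn, trans_fn = trans_fn,
                     entry_cost_fn = entry_cost_fn, init = init,
                     cycle_length_years = cl, tags = tags)
}

#' Build the secondary prevention (relapse) strategy pair
#'
#' Constructs the probiotic-prophylaxis and no-prophylaxis arms of the
#' relapsing-pouchitis model. The arms differ in the annual relapse
#' probability (0.14 vs 0.39 at base case) and in the per-cycle probiotic
#' cost, which in the probiotic arm is accrued in every pre-CARP state
#' (prophylaxis continues through relapses) and stops at CARP entry.
#'
#' @param ps A `parameter_set` for scope `"secondary"`.
#' @return Named list of two `strategy_model`s: `probiotic`,
#'   `no_prophylaxis`.
#' @export
#' @examples
#' arms <- build_secondary(load_defaults("secondary"))
#' tr <- run_cohort(arms$no_prophylaxis, load_defaults("secondary"), 2)
#' tr$event_incidence$ever_ifx[[27]]  # terminal-IFX reach at 2 years
build_secondary <- function(ps) {
  v <- validate_parameters(ps, model = "secondary")
  if (nrow(v)) {
    stop(sprintf("invalid parameter set for secondary model: %s",
                 paste(v$parameter, v$rule, sep = ": ", collapse = "; ")),
         call. = FALSE)
  }
  list(probiotic = .build_secondary_arm("probiotic"),
       no_prophylaxis = .build_secondary_arm("no_prophylaxis"))
}
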
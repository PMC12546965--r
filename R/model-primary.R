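# Primary prevention model: patients with an ileal pouch and no pouchitis
# history, randomised to daily 8-strain probiotic prophylaxis or none, followed
# in 2-week cycles. First episodes are worked up (provider visit, labs, stool
# testing, pouchoscopy) and treated with a ladder of ciprofloxacin ->
# metronidazole -> ciprofloxacin+tinidazole (4-week course, two cycles).
# Responders enter a line-specific remission; recurrences are retreated with
# the previously effective antibiotic and failures escalate one line.
# Probiotic is taken only while pouchitis-free and stopped at the first
# episode.

.primary_states_core <- c("well", "cipro_first", "rem_first", "cipro", "metro",
                          "dual_a", "dual_b", "rem_cipro", "rem_metro",
                          "rem_dual")
.primary_states_bio <- c("vdz_i1", "vdz_i2", "vdz_i3", "vdz_i4",
                         "vdz_m1", "vdz_m2", "vdz_m3", "vdz_md",
                         "ifx_0", "ifx_1", "ifx_2", "ifx_3",
                         "ifx_m1", "ifx_m2", "ifx_m3", "ifx_md")

#' Antibiotic course cost reference and tunnel length
#'
#' Maps a treatment line to the registry parameter holding its course cost
#' and to the number of Markov cycles the course occupies (the 4-week dual
#' course spans two 2-week cycles in the primary model but a single 4-week
#' cycle in the secondary model).
#'
#' @param line One of `"cipro"`, `"metro"`, `"dual"`.
#' @param model `"primary"` or `"secondary"`.
#' @return List with `parameter` (registry name) and `tunnel_cycles`.
#' @export
#' @examples
#' antibiotic_course_cost("dual", "primary")
antibiotic_course_cost <- function(line = c("cipro", "metro", "dual"),
                                   model = c("primary", "secondary")) {
  line <- match.arg(line)
  model <- match.arg(model)
  if (model == "primary") {
    switch(line,
           cipro = list(parameter = "cost_cipro_2wk", tunnel_cycles = 1L),
           metro = list(parameter = "cost_metro_2wk", tunnel_cycles = 1L),
           dual  = list(parameter = "cost_dual_4wk",  tunnel_cycles = 2L))
  } else {
    switch(line,
           cipro = list(parameter = "cost_cipro_4wk", tunnel_cycles = 1L),
           metro = list(parameter = "cost_metro_4wk", tunnel_cycles = 1L),
           dual  = list(parameter = "cost_dual_4wk",  tunnel_cycles = 1L))
  }
}

# shared VDZ/IFX sub-chain wiring used by the extended primary variant
# (2-week grid: doses at cycles 0, 1, 3, then every 4th cycle)
.primary_bio_trans <- function(M, p, cl) {
  rv <- p[["p_resp_vdz"]]
  lor <- to_cycle_probability(p[["p_lor_vdz_annual"]], cl)
  M["vdz_i1", "vdz_i2"] <- 1
  M["vdz_i2", "vdz_i3"] <- 1
  M["vdz_i3", "vdz_i4"] <- 1
  M["vdz_i4", "vdz_m1"] <- rv
  M["vdz_i4", "ifx_0"] <- 1 - rv
  loop <- c("vdz_m1", "vdz_m2", "vdz_m3", "vdz_md")
  nxt <- c(loop[-1], loop[1])
  for (i in seq_along(loop)) {
    M[loop[i], "ifx_0"] <- lor
    M[loop[i], nxt[i]] <- 1 - lor
  }
  chain <- c("ifx_0", "ifx_1", "ifx_2", "ifx_3", "ifx_m1", "ifx_m2", "ifx_m3", "ifx_md")
  for (i in seq_len(length(chain) - 1L)) M[chain[i], chain[i + 1L]] <- 1
  M["ifx_md", "ifx_m1"] <- 1
  M
}

.build_primary_arm <- function(arm = c("probiotic", "no_prophylaxis"),
                               variant, cl = 1 / 26) {
  arm <- match.arg(arm)
  extended <- identical(variant, "extended_biologics")
  empirical <- identical(variant, "empirical_workup")
  ids <- c(.primary_states_core, if (extended) .primary_states_bio)
  S <- length(ids)
  p_first_name <- if (arm == "probiotic") "p_first_pouchitis_ppx_annual" else
    "p_first_pouchitis_no_ppx_annual"

  active <- c("cipro_first", "cipro", "metro", "dual_a", "dual_b",
              if (extended) c("vdz_i1", "vdz_i2", "vdz_i3", "vdz_i4"))
  utility_ref <- stats::setNames(
    ifelse(ids %in% active, "utility_active_pouchitis", "utility_no_pouchitis"),
    ids)

  trans_fn <- function(cycle, ps) {
    p <- ps$values
    pf <- to_cycle_probability(p[[p_first_name]], cl)
    pr <- to_cycle_probability(p[["p_recurrent_pouchitis_annual"]], cl)
    rc <- p[["p_resp_cipro"]]
    rm <- p[["p_resp_metro"]]
    rd <- p[["p_resp_dual"]]
    M <- matrix(0, S, S, dimnames = list(ids, ids))
    M["well", "cipro_first"] <- pf;  M["well", "well"] <- 1 - pf
    M["cipro_first", "rem_first"] <- rc; M["cipro_first", "metro"] <- 1 - rc
    M["rem_first", "cipro"] <- pr;   M["rem_first", "rem_first"] <- 1 - pr
    M["cipro", "rem_cipro"] <- rc;   M["cipro", "metro"] <- 1 - rc
    M["metro", "rem_metro"] <- rm;   M["metro", "dual_a"] <- 1 - rm
    M["dual_a", "dual_b"] <- 1
    M["rem_cipro", "cipro"] <- pr;   M["rem_cipro", "rem_cipro"] <- 1 - pr
    M["rem_metro", "metro"] <- pr;   M["rem_metro", "rem_metro"] <- 1 - pr
    M["rem_dual", "dual_a"] <- pr;   M["rem_dual", "rem_dual"] <- 1 - pr
    M["dual_b", "rem_dual"] <- rd
    if (extended) {
      M["dual_b", "vdz_i1"] <- 1 - rd
      M <- .primary_bio_trans(M, p, cl)
    } else if (rd < 1) {
      stop("dual-antibiotic response < 1 requires the extended_biologics variant",
           call. = FALSE)
    }
    M
  }

  state_cost_fn <- function(ps) {
    p <- ps$values
    cost <- stats::setNames(numeric(S), ids)
    if (arm == "probiotic") cost["well"] <- p[["cost_probiotic_2wk"]]
    if (extended) {
      vdz <- biologic_schedule("VDZ", ps, cycle_length_weeks = 2)
      ifx <- biologic_schedule("IFX", ps, cycle_length_weeks = 2)
      cost["vdz_i1"] <- biologic_cycle_cost(vdz, 0L, ps)
      cost["vdz_i2"] <- biologic_cycle_cost(vdz, 1L, ps)
      cost["vdz_i3"] <- biologic_cycle_cost(vdz, 2L, ps)
      cost["vdz_i4"] <- biologic_cycle_cost(vdz, 3L, ps)
      cost["vdz_md"] <- biologic_cycle_cost(vdz, 7L, ps)
      cost["ifx_0"] <- biologic_cycle_cost(ifx, 0L, ps)
      cost["ifx_1"] <- biologic_cycle_cost(ifx, 1L, ps)
      cost["ifx_3"] <- biologic_cycle_cost(ifx, 3L, ps)
      cost["ifx_md"] <- biologic_cycle_cost(ifx, 7L, ps)
    }
    unname(cost)
  }

  entry_cost_fn <- function(ps) {
    p <- ps$values
    E <- matrix(0, S, S, dimnames = list(ids, ids))
    workup <- p[["cost_first_episode_workup"]]
    cip <- p[["cost_cipro_2wk"]]
    met <- p[["cost_metro_2wk"]]
    dua <- p[["cost_dual_4wk"]]
    if (empirical) {
      # workup deferred to the first recurrence or first antibiotic failure
      E["well", "cipro_first"] <- cip
      E["cipro_first", "metro"] <- workup + met
      E["rem_first", "cipro"] <- workup + cip
    } else {
      E["well", "cipro_first"] <- workup + cip
      E["cipro_first", "metro"] <- met
      E["rem_first", "cipro"] <- cip
    }
    E["cipro", "metro"] <- met
    E["rem_cipro", "cipro"] <- cip
    E["rem_metro", "metro"] <- met
    E["metro", "dual_a"] <- dua
    E["rem_dual", "dual_a"] <- dua
    E
  }

  tags <- list(ever_pouchitis = setdiff(ids, "well"),
               ever_metro = setdiff(ids, c("well", "cipro_first", "rem_first",
                                           "cipro", "rem_cipro")),
               ever_dual = c("dual_a", "dual_b", "rem_dual",
                             if (extended) .primary_states_bio))
  if (extended) {
    tags$ever_biologic <- .primary_states_bio
    tags$ever_ifx <- grep("^ifx", ids, value = TRUE)
  }

  init <- c(1, numeric(S - 1L))
  new_strategy_model(name = paste0("primary_", arm, "_", variant),
                     state_ids = ids, utility_ref = utility_ref,
                     state_cost_fn = state_cost_fn, trans_fn = trans_fn,
                     entry_cost_fn = entry_cost_fn, init = init,
                     cycle_length_years = cl, tags = tags)
}

#' Build the primary prevention strategy pair
#'
#' Constructs the probiotic-prophylaxis and no-prophylaxis arms of the
#' primary prevention model. The arms share the treatment pathway and differ
#' only in the annual first-episode probability (0.1 vs 0.4 at base case) and
#' in the per-cycle probiotic cost accrued while pouchitis-free in the
#' probiotic arm.
#'
#' Variants:
#' \describe{
#'   \item{`base`}{diagnostic workup charged at the first episode;
#'     dual-antibiotic response fixed at 1 (terminal).}
#'   \item{`empirical_workup`}{first episode treated empirically; the workup
#'     cost is deferred to the first recurrence or first antibiotic failure,
#'     whichever comes first. QALYs are identical to `base` at equal
#'     parameters (the variants differ only in cost timing).}
#'   \item{`extended_biologics`}{dual-antibiotic failures continue to
#'     vedolizumab (with loss of response) and then infliximab; requires a
#'     `"primary_extended"` parameter set.}
#' }
#'
#' @param ps A `parameter_set` for scope `"primary"` (or
#'   `"primary_extended"` for the extended variant).
#' @param variant One of `"base"`, `"empirical_workup"`,
#'   `"extended_biologics"`.
#' @return Named list of two `strategy_model`s: `probiotic`,
#'   `no_prophylaxis`.
#' @export
#' @examples
#' arms <- build_primary(load_defaults("primary"))
#' names(arms)
build_primary <- function(ps, variant = c("base", "empirical_workup",
                                          "extended_biologics")) {
  variant <- match.arg(variant)
  scope <- if (variant == "extended_biologics") "primary_extended" else "primary"
  v <- validate_parameters(ps, model = scope)
  if (nrow(v)) {
    stop(sprintf("invalid parameter set for %s model: %s", scope,
                 paste(v$parameter, v$rule, sep = ": ", collapse = "; ")),
         call. = FALSE)
  }
  list(probiotic = .build_primary_arm("probiotic", variant),
       no_prophylaxis = .build_primary_arm("no_prophylaxis", variant))
}
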
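#' Apply a scenario specification to a base configuration
#'
#' Produces a new configuration with declarative overrides applied; the base
#' is untouched and every override is recorded in the returned config's
#' `provenance` attribute. Supported overrides:
#'
#' * `label`: scenario label.
#' * `horizon_cycles`: simulation horizon in monthly cycles (e.g. 18 for the
#'   18-month scenario, 360 for 30 years).
#' * `annual_discount`: discount rate (e.g. 0 or 0.10).
#' * `equal_risk`: character vector among `"cv_death"`, `"noncv_death"`,
#'   `"hhf"`, `"emergency"` — copies the comparator's value for that
#'   transition into the intervention arm (and its sampling mean), modelling
#'   no treatment effect on that risk. `"emergency"` is an alias of `"hhf"`:
#'   the state space merges emergency visits and hospitalizations for HF into
#'   one acute-event state with a single transition probability.
#' * `drug_multiplier`: multiplies the intervention arm's monthly drug cost
#'   (e.g. 0.25, 0.5, 0.75 for the drug-price scenarios).
#' * `wtp`: replacement two-tier threshold list.
#'
#' @param config Base configuration (validated).
#' @param spec Named list of overrides.
#' @return A new validated configuration with `provenance` attribute.
#' @examples
#' cfg <- apply_scenario(taiwan_base_config(),
#'                       list(label = "18 months", horizon_cycles = 18))
#' @export
apply_scenario <- function(config, spec) {
  validate_config(config)
  known <- c("label", "horizon_cycles", "annual_discount", "equal_risk",
             "drug_multiplier", "wtp")
  unknown <- setdiff(names(spec), known)
  if (length(unknown)) {
    stop("unknown scenario override(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(known, collapse = ", "), call. = FALSE)
  }
  prov <- character(0)
  out <- config
  if (!is.null(spec$label)) out$label <- spec$label
  if (!is.null(spec$horizon_cycles)) {
    out$settings$horizon_cycles <- as.integer(spec$horizon_cycles)
    prov <- c(prov, paste0("horizon_cycles=", spec$horizon_cycles))
  }
  if (!is.null(spec$annual_discount)) {
    out$settings$annual_discount <- spec$annual_discount
    prov <- c(prov, paste0("annual_discount=", spec$annual_discount))
  }
  if (!is.null(spec$equal_risk)) {
    valid <- c("cv_death", "noncv_death", "hhf", "emergency")
    bad <- setdiff(spec$equal_risk, valid)
    if (length(bad)) {
      stop("unknown equal_risk flag(s): ", paste(bad, collapse = ", "),
           "; valid flags are: ", paste(valid, collapse = ", "), call. = FALSE)
    }
    flags <- unique(sub("^emergency$", "hhf", spec$equal_risk))
    for (fl in flags) {
      fld <- paste0("p_", fl)
      v <- out$arms[[out$comparator]]$transitions[[fld]]
      out$arms[[out$intervention]]$transitions[[fld]] <- v
      dist_name <- paste0(out$intervention, ".", fld)
      comp_dist <- out$distributions[[paste0(out$comparator, ".", fld)]]
      if (!is.null(out$distributions[[dist_name]]) && !is.null(comp_dist)) {
        out$distributions[[dist_name]] <- comp_dist
      }
      prov <- c(prov, paste0("equal_risk:", fl, "=", v))
    }
  }
  if (!is.null(spec$drug_multiplier)) {
    stopifnot(spec$drug_multiplier >= 0)
    arm <- out$intervention
    out$arms[[arm]]$drug_monthly <- out$arms[[arm]]$drug_monthly * spec$drug_multiplier
    dn <- paste0(arm, ".drug_monthly")
    if (!is.null(out$distributions[[dn]])) {
      out$distributions[[dn]]$mean <- out$distributions[[dn]]$mean * spec$drug_multiplier
      out$distributions[[dn]]$sd <- out$distributions[[dn]]$sd * spec$drug_multiplier
    }
    prov <- c(prov, paste0("drug_multiplier=", spec$drug_multiplier))
  }
  if (!is.null(spec$wtp)) {
    out$wtp <- spec$wtp
    prov <- c(prov, "wtp overridden")
  }
  out <- validate_config(out)
  attr(out, "provenance") <- c(attr(config, "provenance"), prov)
  out
}

#' Run a battery of configurations
#'
#' Runs each configuration through the full two-arm model and collects one
#' row per config: per-arm discounted cost and QALYs, undiscounted life
#' years, increments, ICER per QALY, the willingness-to-pay decision, and
#' optionally the PSA probability of cost-effectiveness at the config's
#' first threshold. A failing config is recorded (with its error message)
#' and the battery continues.
#'
#' @param configs Non-empty list of validated configurations.
#' @param psa_iterations If > 0, additionally run [run_psa()] per config with
#'   this many iterations.
#' @param seed Seed forwarded to the per-config PSA.
#' @return Data frame with one row per configuration.
#' @export
run_battery <- function(configs, psa_iterations = 0, seed = 1L) {
  if (length(configs) == 0) stop("battery needs at least one config", call. = FALSE)
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    res <- tryCatch(run_model(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(label = cfg$label %||% paste0("config_", i),
                        cost_intervention = NA, cost_comparator = NA,
                        delta_cost = NA, qaly_intervention = NA,
                        qaly_comparator = NA, delta_qaly = NA,
                        ly_intervention = NA, ly_comparator = NA,
                        delta_ly = NA, icer_per_qaly = NA_character_,
                        decision = NA_character_, ce_probability = NA,
                        error = conditionMessage(res)))
    }
    cep <- NA_real_
    if (psa_iterations > 0) {
      psa <- run_psa(cfg, iterations = psa_iterations, seed = seed)
      cep <- unname(psa$ce_probability[1])
    }
    inc <- res$incremental
    data.frame(label = cfg$label %||% paste0("config_", i),
               cost_intervention = res$intervention$cost_discounted,
               cost_comparator = res$comparator$cost_discounted,
               delta_cost = inc$delta_cost,
               qaly_intervention = res$intervention$qaly_discounted,
               qaly_comparator = res$comparator$qaly_discounted,
               delta_qaly = inc$delta_qaly,
               ly_intervention = res$intervention$ly_undiscounted,
               ly_comparator = res$comparator$ly_undiscounted,
               delta_ly = inc$delta_ly,
               icer_per_qaly = if (is.character(inc$icer_per_qaly)) {
                 inc$icer_per_qaly
               } else format(inc$icer_per_qaly, digits = 10),
               decision = res$decision,
               ce_probability = cep,
               error = NA_character_)
  })
  do.call(rbind, rows)
}

#' Asia-Pacific country willingness-to-pay profiles
#'
#' One-GDP-per-capita (2020) willingness-to-pay thresholds for the countries
#' covered by the analysis. Country-specific cost and utility sets are
#' user-supplied (they are not part of the public inputs); the profiles
#' carry the thresholds only.
#'
#' @return Data frame with `country` and `wtp_per_qaly` (2020 US$/QALY).
#' @export
country_wtp_profiles <- function() {
  data.frame(
    country = c("Taiwan", "Japan", "Korea", "Singapore", "Australia"),
    wtp_per_qaly = c(25000, 39000, 30000, 58000, 52000)
  )
}
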
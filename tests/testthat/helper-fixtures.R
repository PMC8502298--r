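# Hand-made arm outcome for economics tests (bypasses the engine).
make_outcome <- function(cost, qaly, ly, settings = sim_settings(), arm = "x") {
  structure(
    list(cost_discounted = cost, cost_undiscounted = cost,
         qaly_discounted = qaly, qaly_undiscounted = qaly,
         ly_discounted = ly, ly_undiscounted = ly,
         hhf_events_expected = 0, cumulative_mortality = 0,
         settings = settings, arm = arm),
    class = "arm_outcome")
}

# One claims row in the schema generate_claims() emits.
claim_row <- function(patient_id, date, setting = "ambulatory", hf_dx = TRUE,
                      cost = 0, death_date = NA, death_cause = NA_character_) {
  data.frame(patient_id = patient_id, date = as.Date(date), setting = setting,
             hf_dx = hf_dx, cost = cost,
             death_date = as.Date(death_date, origin = "1970-01-01"),
             death_cause = death_cause)
}

make_claims <- function(...) do.call(rbind, list(...))

# A patient certain to satisfy the stable-cohort filters: monthly ambulatory
# HF claims of `monthly_cost` starting at `index`, for `months` months.
stable_patient <- function(pid, index, months, monthly_cost = 300) {
  index <- as.Date(index)
  do.call(rbind, lapply(seq_len(months) - 1, function(m) {
    claim_row(pid, index + 30 * m, "ambulatory", TRUE, monthly_cost)
  }))
}

table1_sc <- list(p_hhf = 0.007881397, p_cv_death = 0.006698743,
                  p_noncv_death = 0.001312441)

set_param_public <- function(cfg, nm, value) hfcea:::set_param(cfg, nm, value)
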
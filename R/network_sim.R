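# Simulated-network experiments: many DataMarts curated over several
# cycles, with heterogeneous error profiles that reproduce the qualitative
# network patterns -- improvement over time for remediable defects,
# constant membership for structural defects, and churning membership for
# random feed events.

#' Simulate a curated network of DataMarts across cycles
#'
#' Each DataMart runs two refreshes per cycle (so persistence checks are
#' evaluable) and is curated on the cycle's final refresh. Three defect
#' processes are superimposed:
#' * a remediable mapping defect (missing lab units, DC3.12) whose rate
#'   starts at a DataMart-specific level and decays geometrically each
#'   cycle -- prevalence declines over cycles;
#' * a structural defect (no principal-diagnosis flagging, DC2.07) fixed in
#'   a constant subset of DataMarts -- constant prevalence, identical
#'   membership;
#' * random feed-loss events (probability `feed_event_prob` per DataMart
#'   and cycle, magnitude `feed_magnitude`) -- stable prevalence with
#'   changing membership on DC4.01.
#'
#' @param n_datamarts,n_cycles network size.
#' @param n_patients population per DataMart.
#' @param seed integer seed; the whole simulation is deterministic in it.
#' @param unit_rate_range range of the cycle-1 missing-lab-unit rate.
#' @param unit_decay per-cycle multiplicative decay of that rate.
#' @param structural_fraction fraction of DataMarts with the structural
#'   principal-diagnosis defect.
#' @param feed_event_prob,feed_magnitude feed-loss event process.
#' @param catalog,schema catalog and schema used for curation.
#' @return list with `outcomes` (cycle label -> list of
#'   `curation_outcome`), and `truth` (the simulated ground truth:
#'   `structural_datamarts`, `unit_rates` matrix, `feed_events` logical
#'   matrix).
#' @export
simulate_network <- function(n_datamarts = 20, n_cycles = 6, n_patients = 80,
                             seed = 1L, unit_rate_range = c(0.03, 0.40),
                             unit_decay = 0.5, structural_fraction = 0.3,
                             feed_event_prob = 0.3, feed_magnitude = 0.2,
                             catalog = load_catalog(), schema = load_schema()) {
  base_start <- as.Date("2021-01-01")
  base_end <- as.Date("2023-12-31")
  draws <- with_seed(seed, list(
    unit_rate0 = stats::runif(n_datamarts, unit_rate_range[1], unit_rate_range[2]),
    feed_events = matrix(stats::runif(n_datamarts * n_cycles) < feed_event_prob,
                         nrow = n_datamarts)))
  structural <- seq_len(max(0L, round(structural_fraction * n_datamarts)))
  mart_ids <- sprintf("DM%02d", seq_len(n_datamarts))
  unit_rates <- outer(draws$unit_rate0, unit_decay^(seq_len(n_cycles) - 1L))
  dimnames(unit_rates) <- list(mart_ids, paste0("cycle", seq_len(n_cycles)))
  dimnames(draws$feed_events) <- dimnames(unit_rates)

  outcomes <- list()
  for (cy in seq_len(n_cycles)) {
    label <- paste0("cycle", cy)
    outcomes[[label]] <- lapply(seq_len(n_datamarts), function(i) {
      pop <- population_config(
        n_patients = n_patients,
        date_range = c(base_start, shift_months_eom(base_end, 6 * (cy - 1L))),
        seed = (seed + 7717L * i + 131L * cy) %% .Machine$integer.max)
      errors <- error_profile(
        missing_lab_unit_rate = unit_rates[i, cy],
        missing_principal_rate = if (i %in% structural) 1 else 0)
      events <- if (draws$feed_events[i, cy]) {
        list(list(ordinal = 2L, kind = "feed_loss", magnitude = feed_magnitude))
      } else list()
      hist <- generate_refresh_sequence(
        pop, errors, refresh_scenario(n_refreshes = 2L, events = events),
        schema, datamart_id = mart_ids[i])
      n <- length(hist$refreshes)
      run_curation(hist$refreshes[[n]], hist$refreshes[-n], catalog, schema)
    })
  }
  list(outcomes = outcomes,
       truth = list(structural_datamarts = mart_ids[structural],
                    unit_rates = unit_rates, feed_events = draws$feed_events))
}

#' Per-cycle exception prevalence of one check across a simulated network
#'
#' @param outcomes_by_cycle as returned in `simulate_network()$outcomes`.
#' @param check_id the check of interest.
#' @return data frame `cycle`, `n_applicable`, `n_exceptions`, `percent`,
#'   plus a `failing` list-column of DataMart ids with the exception.
#' @export
check_prevalence <- function(outcomes_by_cycle, check_id) {
  rows <- lapply(names(outcomes_by_cycle), function(cy) {
    outs <- outcomes_by_cycle[[cy]]
    cr <- rbind_all(lapply(outs, function(o) {
      r <- o$check_results
      cbind(r[r$check_id == check_id, , drop = FALSE], datamart_id = o$datamart_id)
    }))
    applicable <- cr$n_measures > cr$n_not_applicable
    failing <- cr$datamart_id[cr$exception]
    out <- data.frame(cycle = cy, n_applicable = sum(applicable),
                      n_exceptions = sum(cr$exception[applicable]),
                      percent = 100 * sum(cr$exception[applicable]) /
                        max(1L, sum(applicable)),
                      stringsAsFactors = FALSE)
    out$failing <- list(failing)
    out
  })
  rbind_all(rows)
}
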
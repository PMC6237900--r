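# Endpoint coding for the prognosis (PM) and adjuvant-therapy-selection
# (AT) modules. PM endpoints code the three prognostic outcomes at the
# horizon; AT endpoints reverse the order for chemotherapy-treated (CTX)
# patients, encoding the hypothesis that high-risk CTX patients would have
# fared better under chemoradiation (CCRT) and vice versa.

#' Assign prognosis-module endpoints
#'
#' Codes each patient at the horizon: 2 = recurred within the horizon
#' (event at the observed DFS), 1 = censored before the horizon (censored
#' at the observed DFS), 0 = no recurrence through the horizon (censored at
#' the horizon). An event recorded after the horizon counts as no
#' recurrence within it (endpoint 0) and is messaged.
#'
#' @param clinical clinical table (`patient_id`, `dfs_months`, `event`, ...).
#' @param horizon months, default 72 (6 years).
#' @return data.frame `patient_id`, `pm_endpoint` (0/1/2), `derived_time`,
#'   `derived_event`.
#' @export
assign_pm_endpoints <- function(clinical, horizon = 72) {
  stopifnot(all(c("patient_id", "dfs_months", "event") %in% names(clinical)))
  t <- clinical$dfs_months
  e <- clinical$event
  late_event <- e == 1L & t > horizon
  if (any(late_event)) {
    message(sum(late_event),
            " event(s) after the horizon treated as no recurrence within it")
  }
  pm <- ifelse(e == 1L & t <= horizon, 2L, ifelse(t < horizon, 1L, 0L))
  data.frame(
    patient_id = clinical$patient_id,
    pm_endpoint = pm,
    derived_time = ifelse(pm == 0L, horizon, pmin(t, horizon)),
    derived_event = as.integer(pm == 2L),
    stringsAsFactors = FALSE
  )
}

#' Assign adjuvant-therapy-selection endpoints
#'
#' CCRT-treated patients keep their PM endpoint, derived time and event.
#' CTX-treated patients get the reversed code `2 - pm`: a patient without
#' recurrence through the horizon (pm 0) becomes an AT event at the horizon
#' (at 2); a recurrence (pm 2) becomes a censoring at the observed
#' recurrence time (at 0); early censoring (pm 1) is unchanged.
#'
#' @param endpoints result of [assign_pm_endpoints()].
#' @param clinical clinical table carrying the `arm` column
#'   (`"CTX"`/`"CCRT"`).
#' @param horizon months, default 72.
#' @return the endpoint table with `at_endpoint`, `at_time`, `at_event`
#'   columns added.
#' @export
assign_at_endpoints <- function(endpoints, clinical, horizon = 72) {
  stopifnot(identical(endpoints$patient_id, clinical$patient_id))
  arm <- clinical$arm
  if (!all(arm %in% c("CTX", "CCRT"))) {
    stop("unknown adjuvant arm; expected CTX or CCRT", call. = FALSE)
  }
  pm <- endpoints$pm_endpoint
  at <- ifelse(arm == "CTX", 2L - pm, pm)
  at_time <- endpoints$derived_time
  at_event <- endpoints$derived_event
  ctx <- arm == "CTX"
  # reversed outcomes: at 2 (was no recurrence) -> event at horizon;
  # at 0 (was recurrence) -> censored at the recurrence time
  at_time[ctx & at == 2L] <- horizon
  at_event[ctx] <- as.integer(at[ctx] == 2L)
  endpoints$at_endpoint <- at
  endpoints$at_time <- at_time
  endpoints$at_event <- at_event
  endpoints
}
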
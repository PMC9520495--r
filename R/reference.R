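# Published composition of the Swedish register cohorts the generator
# emulates.

#' Published register cohort composition
#'
#' Baseline characteristics of the two nationwide Swedish PSA-register
#' cohorts behind the model: 7263 men reaching the castration-sensitive
#' state and 3899 reaching the castration-resistant state, tabulated by
#' age band at state entry, Charlson Comorbidity Index, treatment
#' history and merged risk-category group. Used to calibrate the
#' synthetic generator's demographic defaults and as the anchor for
#' exact percentage checks.
#'
#' @return data.frame with columns `state` (`"CSPC"`/`"CRPC"`),
#'   `variable`, `level`, `n`; the per-state totals are the rows with
#'   `variable == "total"`.
#' @export
swedish_registry_reference <- function() {
  rbind(
    data.frame(state = "CSPC", variable = "total", level = "all", n = 7263L),
    data.frame(state = "CRPC", variable = "total", level = "all", n = 3899L),
    data.frame(state = "CSPC", variable = "age_band",
               level = c("<=65", "66-75", "76-85", ">=86"),
               n = c(809L, 2196L, 3230L, 1028L)),
    data.frame(state = "CRPC", variable = "age_band",
               level = c("<=65", "66-75", "76-85", ">=86"),
               n = c(432L, 1192L, 1629L, 646L)),
    data.frame(state = "CSPC", variable = "cci",
               level = c("0", "1", "2", "3+"),
               n = c(4556L, 1174L, 647L, 886L)),
    data.frame(state = "CRPC", variable = "cci",
               level = c("0", "1", "2", "3+"),
               n = c(2398L, 630L, 375L, 496L)),
    data.frame(state = "CSPC", variable = "treatment_history",
               level = c("Primary GnRH", "AA -> GnRH", "WW -> AA -> GnRH",
                         "WW -> GnRH", "RP -> AA -> GnRH", "RT -> AA -> GnRH",
                         "RP -> GnRH", "RT -> GnRH"),
               n = c(4543L, 683L, 204L, 885L, 162L, 142L, 208L, 436L)),
    data.frame(state = "CRPC", variable = "treatment_history",
               level = c("Primary GnRH", "AA -> GnRH", "WW -> AA -> GnRH",
                         "WW -> GnRH", "RP -> AA -> GnRH", "RT -> AA -> GnRH",
                         "RP -> GnRH", "RT -> GnRH"),
               n = c(2556L, 463L, 102L, 328L, 82L, 90L, 86L, 192L)),
    data.frame(state = "CSPC", variable = "risk_category_group",
               level = c("1-2", "3-4", "5-6", "7-8"),
               n = c(2119L, 2715L, 1329L, 1100L)),
    data.frame(state = "CRPC", variable = "risk_category_group",
               level = c("1-2", "3-4", "5-6", "7-8"),
               n = c(849L, 1147L, 963L, 940L))
  )
}
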
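# Discrete-time transition hazards: per-28-day logistic models for
# CSPC -> CRPC, CSPC -> PCa death and CRPC -> PCa death (cause-specific:
# competing events in the same period are non-events for the transition
# being fitted), plus the other-cause mortality table stratified by age
# band and comorbidity.

.TRANSITIONS <- c(cspc_to_crpc = "to_CRPC",
                  cspc_to_pca_death = "pca_death",
                  crpc_to_pca_death = "pca_death")
.TRANSITION_STATE <- c(cspc_to_crpc = "CSPC",
                       cspc_to_pca_death = "CSPC",
                       crpc_to_pca_death = "CRPC")

.covariate_levels <- function() {
  list(risk_category = as.character(1:8), age_band = .AGE_BANDS,
       cci = .CCI_LEVELS, time_in_state_band = .TIS_BANDS)
}

#' Fit a per-28-day logistic transition model
#'
#' Maximum-likelihood logistic regression of the period event indicator
#' on categorical covariates over all at-risk person-periods in the
#' transition's origin state. Competing events occurring in the same
#' period are treated as non-events for this transition (cause-specific
#' hazards, recombined at simulation time). Factor encodings always
#' carry the full level sets (risk category 1..8, four age bands, four
#' CCI classes, five time-in-state bands); levels absent from the
#' training data get coefficient 0 with a warning so predictions remain
#' defined.
#'
#' @param person_periods data.frame from [expand_person_periods()].
#' @param transition one of `"cspc_to_crpc"`, `"cspc_to_pca_death"`,
#'   `"crpc_to_pca_death"`.
#' @param covariates character vector of covariate columns (subset of
#'   `risk_category`, `age_band`, `cci`, `time_in_state_band`); empty for
#'   an intercept-only model.
#' @param training_label optional label stored in the metadata (e.g. the
#'   training cohort).
#' @return object of class `transition_model` with elements
#'   `coefficients`, `xlevels`, `covariates`, `transition`,
#'   `origin_state`, `event_type`, `training_meta`.
#' @export
fit_transition_model <- function(person_periods,
                                 transition = names(.TRANSITIONS),
                                 covariates = c("risk_category", "age_band",
                                                "cci", "time_in_state_band"),
                                 training_label = NA_character_) {
  transition <- match.arg(transition)
  origin <- .TRANSITION_STATE[[transition]]
  ev <- .TRANSITIONS[[transition]]
  pp <- person_periods[person_periods$state == origin, , drop = FALSE]
  if (nrow(pp) == 0) {
    .crpc_error("crpcstates_no_data", sprintf("no person-periods in state %s", origin))
  }
  y <- as.integer(pp$event == ev)
  if (sum(y) == 0) {
    .crpc_error("crpcstates_no_events",
                sprintf("zero %s events among %d periods at risk", ev, nrow(pp)))
  }
  lv <- .covariate_levels()
  dat <- data.frame(y = y)
  for (cv in covariates) {
    dat[[cv]] <- factor(as.character(pp[[cv]]), levels = lv[[cv]])
    if (anyNA(dat[[cv]])) {
      .crpc_error("crpcstates_unknown_level",
                  sprintf("covariate '%s' has values outside its level set", cv))
    }
  }
  form <- if (length(covariates) == 0) y ~ 1 else
    stats::as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = dat))
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    warning(sprintf("transition %s: %d unestimable level(s) set to coefficient 0",
                    transition, sum(is.na(coefs))), call. = FALSE)
    coefs[is.na(coefs)] <- 0
  }
  # runaway coefficients signal separation: a level whose periods are all
  # events or all non-events. With plenty of data that is genuine
  # complete separation and a named error; in a sparse cell it is a
  # small-sample artifact, so the cell probability is replaced by its
  # Laplace-smoothed empirical fraction instead.
  big <- coefs[names(coefs) != "(Intercept)"]
  runaway <- names(big)[abs(big) > 15]
  for (nm in runaway) {
    cv <- covariates[vapply(covariates, function(c) startsWith(nm, c), logical(1))]
    cv <- cv[which.max(nchar(cv))]
    level <- substring(nm, nchar(cv) + 1)
    at <- as.character(dat[[cv]]) == level
    trials <- sum(at); events <- sum(y[at])
    if (trials >= 20 && (events == trials || events == 0) && big[[nm]] > 15) {
      .crpc_error("crpcstates_separation",
                  sprintf("complete separation on covariate '%s' (level %s: %d/%d events)",
                          cv, level, events, trials))
    }
    smoothed <- stats::qlogis((events + 0.5) / (trials + 1))
    warning(sprintf("transition %s: sparse level %s (%d/%d events); cell probability smoothed",
                    transition, nm, events, trials), call. = FALSE)
    coefs[nm] <- smoothed - coefs[["(Intercept)"]]
  }
  if (!fit$converged) {
    .crpc_error("crpcstates_separation",
                "logistic fit failed to converge (possible separation)")
  }
  structure(list(transition = transition, origin_state = origin,
                 event_type = ev, covariates = covariates,
                 coefficients = coefs,
                 xlevels = lv[covariates],
                 training_meta = list(label = training_label,
                                      n_periods = nrow(pp),
                                      n_events = sum(y),
                                      converged = fit$converged),
                 vcov = stats::vcov(fit)),
            class = "transition_model")
}

#' Intercept-only transition model with a fixed period probability
#'
#' Convenience constructor used for scenario analysis and engine
#' verification: a model whose every prediction is `probability`
#' (including exactly 0).
#'
#' @param transition transition name as in [fit_transition_model()].
#' @param probability constant per-28-day probability in `[0, 1)`.
#' @return a `transition_model`.
#' @export
constant_transition_model <- function(transition = names(.TRANSITIONS),
                                      probability) {
  transition <- match.arg(transition)
  stopifnot(probability >= 0, probability < 1)
  structure(list(transition = transition,
                 origin_state = .TRANSITION_STATE[[transition]],
                 event_type = .TRANSITIONS[[transition]],
                 covariates = character(0),
                 coefficients = c("(Intercept)" = stats::qlogis(probability)),
                 xlevels = list(),
                 training_meta = list(label = "constant", n_periods = NA_integer_,
                                      n_events = NA_integer_, converged = TRUE),
                 vcov = NULL),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %s (%s -> %s)\n", x$transition,
              x$origin_state, x$event_type))
  cat(sprintf("  periods: %s  events: %s\n",
              format(x$training_meta$n_periods), format(x$training_meta$n_events)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict a per-28-day transition probability
#'
#' Inverse-logit of the linear predictor for each covariate row. Rows
#' must use levels from the model's encoding; an unknown level is a
#' named error.
#'
#' @param model a `transition_model`.
#' @param newdata data.frame with the model's covariate columns (ignored
#'   for intercept-only models).
#' @return numeric vector of probabilities.
#' @export
predict_period_probability <- function(model, newdata) {
  stopifnot(inherits(model, "transition_model"))
  n <- if (length(model$covariates) == 0) {
    if (missing(newdata) || is.null(newdata)) 1L else max(1L, nrow(newdata))
  } else nrow(newdata)
  lp <- rep(unname(model$coefficients["(Intercept)"]), n)
  for (cv in model$covariates) {
    vals <- as.character(newdata[[cv]])
    if (any(!vals %in% model$xlevels[[cv]])) {
      .crpc_error("crpcstates_unknown_level",
                  sprintf("unknown level for covariate '%s': %s", cv,
                          paste(unique(setdiff(vals, model$xlevels[[cv]])),
                                collapse = ", ")))
    }
    nm <- paste0(cv, vals)
    beta <- model$coefficients[nm]
    beta[is.na(beta)] <- 0  # reference level has no coefficient
    lp <- lp + unname(beta)
  }
  stats::plogis(lp)
}

#' Other-cause mortality table by age band and comorbidity
#'
#' Cell-wise empirical per-28-day probability of other-cause death with
#' additive (Laplace) smoothing: `(d + s) / (n + 2 s)` with `s = 0.5` by
#' default. All person-periods contribute regardless of disease state.
#' An empty cell falls back to the smoothing prior (0.5) with a warning.
#' The table can also be supplied from a file to stand in for an
#' externally estimated background-mortality model.
#'
#' @param person_periods data.frame from [expand_person_periods()].
#' @param smoothing additive smoothing constant (default 0.5).
#' @return object of class `hazard_table`: data.frame `age_band`, `cci`,
#'   `prob`, `n_periods`, `n_events` (16 rows).
#' @export
estimate_other_cause_hazard <- function(person_periods, smoothing = 0.5) {
  grid <- expand.grid(age_band = .AGE_BANDS, cci = .CCI_LEVELS,
                      stringsAsFactors = FALSE)
  key_pp <- paste(person_periods$age_band, person_periods$cci)
  key_grid <- paste(grid$age_band, grid$cci)
  n <- as.integer(table(factor(key_pp, levels = key_grid)))
  d <- as.integer(table(factor(key_pp[person_periods$event == "other_death"],
                               levels = key_grid)))
  if (any(n == 0)) {
    warning(sprintf("%d empty (age band x CCI) cell(s); smoothed prior used",
                    sum(n == 0)), call. = FALSE)
  }
  grid$prob <- (d + smoothing) / (n + 2 * smoothing)
  grid$n_periods <- n
  grid$n_events <- d
  structure(grid, class = c("hazard_table", "data.frame"))
}

#' Constant other-cause hazard table
#'
#' All 16 (age band x CCI) cells set to one probability; `0` disables
#' other-cause mortality in a simulation.
#'
#' @param prob per-28-day probability in `[0, 1)`.
#' @return a `hazard_table`.
#' @export
constant_hazard_table <- function(prob = 0) {
  stopifnot(prob >= 0, prob < 1)
  grid <- expand.grid(age_band = .AGE_BANDS, cci = .CCI_LEVELS,
                      stringsAsFactors = FALSE)
  grid$prob <- prob
  grid$n_periods <- NA_integer_
  grid$n_events <- NA_integer_
  structure(grid, class = c("hazard_table", "data.frame"))
}

#' Read / write an other-cause hazard table
#'
#' CSV round trip (columns `age_band`, `cci`, `prob`), so a table
#' estimated elsewhere can be dropped in unchanged.
#'
#' @param table a `hazard_table`.
#' @param path CSV file path.
#' @return `write_hazard_table()`: invisibly `path`;
#'   `read_hazard_table()`: the table.
#' @export
write_hazard_table <- function(table, path) {
  out <- as.data.frame(table)[, c("age_band", "cci", "prob")]
  out$prob <- formatC(out$prob, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_hazard_table
#' @export
read_hazard_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  stopifnot(all(c("age_band", "cci", "prob") %in% names(tab)))
  tab$prob <- as.numeric(tab$prob)
  if (any(tab$prob < 0 | tab$prob >= 1)) {
    .crpc_error("crpcstates_bad_input", "hazard probabilities must lie in [0, 1)")
  }
  tab$n_periods <- NA_integer_
  tab$n_events <- NA_integer_
  structure(tab, class = c("hazard_table", "data.frame"))
}

# Probability lookup for a hazard table: 4x4 matrix [age band, cci].
.hazard_matrix <- function(table) {
  m <- matrix(NA_real_, 4, 4, dimnames = list(.AGE_BANDS, .CCI_LEVELS))
  m[cbind(match(table$age_band, .AGE_BANDS), match(table$cci, .CCI_LEVELS))] <-
    table$prob
  if (anyNA(m)) .crpc_error("crpcstates_bad_input",
                            "hazard table does not cover all 16 cells")
  m
}
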
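# Registry data model: construction, CSV interchange and validation.
#
# A cohort is the in-memory registry: five tables keyed by patient_id.
# Files are UTF-8 CSV with ISO-8601 dates; missing dates/causes are empty
# fields. This layout is the package's own interchange contract — the
# national register extracts it emulates are not publicly deposited.

.cohort_tables <- c("patients", "psa", "dispensations", "surgeries", "vitals")

.cohort_columns <- list(
  patients = c("patient_id", "birth_year", "diagnosis_date", "cci",
               "treatment_history", "cohort"),
  psa = c("patient_id", "date", "value"),
  dispensations = c("patient_id", "date", "drug_class", "days_supply"),
  surgeries = c("patient_id", "orchidectomy_date"),
  vitals = c("patient_id", "death_date", "cause", "censor_date")
)

.cohort_date_columns <- list(
  patients = "diagnosis_date", psa = "date", dispensations = "date",
  surgeries = "orchidectomy_date", vitals = c("death_date", "censor_date")
)

#' Assemble a registry cohort from its five component tables
#'
#' Builds the in-memory registry object consumed by the rest of the
#' pipeline: patients with their longitudinal PSA, GnRH/antiandrogen
#' dispensations, orchidectomy records and vital status. Column types are
#' coerced (dates to `Date`, days of supply to integer) and PSA records
#' are sorted by patient and date. Duplicate PSA measurements for one
#' patient on one date are collapsed to the minimum value with a warning
#' (conservative for the running nadir).
#'
#' @param patients data.frame with columns `patient_id`, `birth_year`,
#'   `diagnosis_date`, `cci` (one of `"0","1","2","3+"`),
#'   `treatment_history`, `cohort` (`"A"` or `"B"`).
#' @param psa data.frame with columns `patient_id`, `date`, `value`
#'   (ng/ml).
#' @param dispensations data.frame with columns `patient_id`, `date`,
#'   `drug_class` (`"GnRH"` or `"antiandrogen"`), `days_supply`.
#' @param surgeries data.frame with columns `patient_id`,
#'   `orchidectomy_date`.
#' @param vitals data.frame with columns `patient_id`, `death_date`
#'   (`NA` if alive), `cause` (`"PCa"`/`"other"`, `NA` if alive),
#'   `censor_date`.
#' @return an object of class `crpc_cohort`: a named list of the five
#'   normalised tables.
#' @seealso [read_cohort()], [write_cohort()], [validate_cohort()]
#' @export
cohort <- function(patients, psa, dispensations, surgeries, vitals) {
  tabs <- list(patients = patients, psa = psa, dispensations = dispensations,
               surgeries = surgeries, vitals = vitals)
  for (nm in .cohort_tables) {
    tab <- as.data.frame(tabs[[nm]], stringsAsFactors = FALSE)
    missing_cols <- setdiff(.cohort_columns[[nm]], names(tab))
    if (length(missing_cols) > 0) {
      .crpc_error("crpcstates_unknown_column",
                  sprintf("table '%s' lacks column(s): %s", nm,
                          paste(missing_cols, collapse = ", ")))
    }
    tab <- tab[, .cohort_columns[[nm]], drop = FALSE]
    for (dc in .cohort_date_columns[[nm]]) {
      if (!inherits(tab[[dc]], "Date")) {
        raw <- as.character(tab[[dc]])
        parsed <- as.Date(raw, format = "%Y-%m-%d")
        bad <- which(!is.na(raw) & nzchar(raw) & is.na(parsed))
        if (length(bad) > 0) {
          .crpc_error("crpcstates_bad_date",
                      sprintf("table '%s', column '%s': unparseable date in row(s) %s",
                              nm, dc, paste(utils::head(bad, 5), collapse = ", ")))
        }
        tab[[dc]] <- parsed
      }
    }
    tabs[[nm]] <- tab
  }
  tabs$patients$patient_id <- as.character(tabs$patients$patient_id)
  tabs$patients$birth_year <- as.integer(tabs$patients$birth_year)
  tabs$patients$cci <- as.character(tabs$patients$cci)
  tabs$psa$value <- as.numeric(tabs$psa$value)
  tabs$dispensations$days_supply <- as.integer(tabs$dispensations$days_supply)
  for (nm in .cohort_tables) {
    tabs[[nm]]$patient_id <- as.character(tabs[[nm]]$patient_id)
  }
  if (anyDuplicated(tabs$patients$patient_id)) {
    dup <- unique(tabs$patients$patient_id[duplicated(tabs$patients$patient_id)])
    .crpc_error("crpcstates_duplicate_id",
                sprintf("duplicate patient_id in patients table: %s",
                        paste(utils::head(dup, 5), collapse = ", ")))
  }
  # sort PSA; collapse same-day duplicates to the minimum value
  ord <- order(tabs$psa$patient_id, tabs$psa$date, tabs$psa$value)
  tabs$psa <- tabs$psa[ord, , drop = FALSE]
  dup <- duplicated(tabs$psa[, c("patient_id", "date")])
  if (any(dup)) {
    warning(sprintf("%d duplicate same-day PSA measurement(s) collapsed to the minimum value",
                    sum(dup)), call. = FALSE)
    tabs$psa <- tabs$psa[!dup, , drop = FALSE]
  }
  rownames(tabs$psa) <- NULL
  structure(tabs, class = "crpc_cohort")
}

#' @export
print.crpc_cohort <- function(x, ...) {
  cat("<crpc_cohort>\n")
  cat(sprintf("  patients:      %6d\n", nrow(x$patients)))
  cat(sprintf("  psa:           %6d\n", nrow(x$psa)))
  cat(sprintf("  dispensations: %6d\n", nrow(x$dispensations)))
  cat(sprintf("  surgeries:     %6d\n", nrow(x$surgeries)))
  cat(sprintf("  vitals:        %6d\n", nrow(x$vitals)))
  invisible(x)
}

#' Read a registry cohort from a directory of CSV tables
#'
#' Expects `patients.csv`, `psa.csv`, `dispensations.csv`,
#' `surgeries.csv`, `vitals.csv` under `dir` (individual paths can be
#' overridden through `paths`). All invariants are checked after reading;
#' any violating row aborts the read with a row-level report.
#'
#' @param dir directory holding the five tables.
#' @param paths optional named character vector overriding individual
#'   table paths.
#' @return a validated [cohort()] object.
#' @export
read_cohort <- function(dir, paths = NULL) {
  files <- stats::setNames(file.path(dir, paste0(.cohort_tables, ".csv")),
                           .cohort_tables)
  if (!is.null(paths)) files[names(paths)] <- paths
  tabs <- list()
  for (nm in .cohort_tables) {
    if (!file.exists(files[[nm]])) {
      .crpc_error("crpcstates_missing_file",
                  sprintf("missing input file for table '%s': %s", nm, files[[nm]]))
    }
    tab <- utils::read.csv(files[[nm]], colClasses = "character",
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
    extra <- setdiff(names(tab), .cohort_columns[[nm]])
    if (length(extra) > 0) {
      .crpc_error("crpcstates_unknown_column",
                  sprintf("table '%s' has unknown column(s): %s", nm,
                          paste(extra, collapse = ", ")))
    }
    tab[tab == ""] <- NA
    tabs[[nm]] <- tab
  }
  coh <- cohort(tabs$patients, tabs$psa, tabs$dispensations, tabs$surgeries,
                tabs$vitals)
  viol <- validate_cohort(coh)
  if (nrow(viol) > 0) {
    .crpc_error("crpcstates_invalid_rows",
                paste0("cohort fails validation:\n",
                       paste(utils::capture.output(print(utils::head(viol, 20))),
                             collapse = "\n")),
                violations = viol)
  }
  coh
}

#' Write a registry cohort to a directory of CSV tables
#'
#' Inverse of [read_cohort()]: writes the five tables as UTF-8 CSV with
#' ISO-8601 dates and full-precision PSA values, so that a write/read
#' round trip reproduces every record exactly.
#'
#' @param cohort a `crpc_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "crpc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in .cohort_tables) {
    tab <- cohort[[nm]]
    out <- tab
    for (cl in names(out)) {
      if (inherits(out[[cl]], "Date")) {
        out[[cl]] <- ifelse(is.na(out[[cl]]), "", format(out[[cl]], "%Y-%m-%d"))
      } else if (is.double(out[[cl]])) {
        out[[cl]] <- ifelse(is.na(out[[cl]]), "",
                            formatC(out[[cl]], digits = 17, format = "g"))
      }
    }
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(out, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
    files[nm] <- path
  }
  invisible(files)
}

#' Check all registry invariants and report violations
#'
#' A pure reporting function: returns one row per violated rule, naming
#' the table, the patient and the rule. An empty report means the cohort
#' satisfies every invariant. Checked rules include positive finite PSA,
#' days of supply in 1..365, valid CCI/drug/cause codes, birth year before
#' diagnosis, at most one surgery and one vital record per patient,
#' death date not after the censor date, no PSA recorded after death, and
#' referential integrity of every patient_id.
#'
#' @param cohort a `crpc_cohort`.
#' @return data.frame with columns `table`, `patient_id`, `rule`,
#'   `detail`; zero rows when valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "crpc_cohort"))
  v <- list()
  add <- function(table, patient_id, rule, detail = "") {
    if (length(patient_id) > 0) {
      v[[length(v) + 1]] <<- data.frame(table = table,
                                        patient_id = as.character(patient_id),
                                        rule = rule, detail = detail,
                                        stringsAsFactors = FALSE)
    }
  }
  p <- cohort$patients
  add("patients", p$patient_id[!p$cci %in% .CCI_LEVELS], "invalid CCI class")
  add("patients", p$patient_id[!is.na(p$diagnosis_date) &
                                 p$birth_year >= as.integer(format(p$diagnosis_date, "%Y"))],
      "birth_year not before diagnosis year")
  add("patients", p$patient_id[is.na(p$diagnosis_date)], "missing diagnosis_date")
  known <- p$patient_id
  ps <- cohort$psa
  add("psa", ps$patient_id[!is.finite(ps$value) | ps$value <= 0],
      "PSA value not positive and finite")
  add("psa", ps$patient_id[is.na(ps$date)], "missing PSA date")
  add("psa", setdiff(unique(ps$patient_id), known), "unknown patient")
  d <- cohort$dispensations
  add("dispensations", d$patient_id[is.na(d$days_supply) | d$days_supply < 1 |
                                      d$days_supply > 365],
      "days_supply outside [1, 365]")
  add("dispensations", d$patient_id[!d$drug_class %in% .DRUG_CLASSES],
      "invalid drug_class")
  add("dispensations", setdiff(unique(d$patient_id), known), "unknown patient")
  s <- cohort$surgeries
  add("surgeries", unique(s$patient_id[duplicated(s$patient_id)]),
      "more than one orchidectomy record")
  add("surgeries", setdiff(unique(s$patient_id), known), "unknown patient")
  vt <- cohort$vitals
  add("vitals", unique(vt$patient_id[duplicated(vt$patient_id)]),
      "more than one vital record")
  add("vitals", setdiff(unique(vt$patient_id), known), "unknown patient")
  add("vitals", vt$patient_id[!is.na(vt$death_date) &
                                (is.na(vt$cause) | !vt$cause %in% .CAUSES)],
      "death without valid cause")
  add("vitals", vt$patient_id[is.na(vt$death_date) & !is.na(vt$cause)],
      "cause recorded without death date")
  add("vitals", vt$patient_id[is.na(vt$censor_date)], "missing censor_date")
  add("vitals", vt$patient_id[!is.na(vt$death_date) & !is.na(vt$censor_date) &
                                vt$death_date > vt$censor_date],
      "death_date after censor_date")
  # PSA recorded after death
  dead <- vt[!is.na(vt$death_date), c("patient_id", "death_date")]
  if (nrow(dead) > 0 && nrow(ps) > 0) {
    mdeath <- dead$death_date[match(ps$patient_id, dead$patient_id)]
    add("psa", unique(ps$patient_id[!is.na(mdeath) & !is.na(ps$date) &
                                      ps$date > mdeath]),
        "PSA after death")
  }
  if (length(v) == 0) {
    return(data.frame(table = character(0), patient_id = character(0),
                      rule = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
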
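## Dataset reading/writing/validation and analysis configuration.
##
## Event tables use a NONMEM-style long format: one row per dose or
## observation, comma-separated, "." for missing. Default column names:
## ID, TIME, EVID, AMT, DV, MDV, BLQ, LLOQ, OCC, DRUG plus covariate columns
## (SEX, WT, HT, HIV, ART, AGE, ALB, TPROT, ALCOHOL, DIABETES, PREVINH).

.et_schema_default <- c(
  id = "ID", time = "TIME", evid = "EVID", amt = "AMT", dv = "DV",
  mdv = "MDV", blq = "BLQ", lloq = "LLOQ", occasion = "OCC", drug = "DRUG",
  sex = "SEX", weight = "WT", height = "HT", hiv_positive = "HIV",
  art_class = "ART", age = "AGE", albumin = "ALB", total_protein = "TPROT",
  alcohol = "ALCOHOL", diabetes = "DIABETES", prev_inh = "PREVINH"
)

.et_mandatory <- c("id", "time", "evid", "amt", "dv", "blq", "lloq", "occasion", "drug")

#' Read and validate an event table
#'
#' Reads a comma-separated NONMEM-style dataset ("." for missing) and
#' validates it. Validation is total: the result is either a fully valid
#' table or an error listing every offending row - never a partial table.
#'
#' Invariants checked: times non-negative and non-decreasing within subject;
#' `blq` implies a missing concentration and a present LLOQ; every
#' observation carries exactly one occasion (`PREDOSE` or `INTENSIVE`); no
#' record is both a dose and an observation.
#'
#' @param path file path.
#' @param schema named character vector mapping canonical names (`id`,
#'   `time`, `evid`, `amt`, `dv`, `blq`, `lloq`, `occasion`, `drug`, ...) to
#'   the file's column names; defaults to the dialect written by
#'   [write_event_table()].
#' @return data frame of class `tbpk_event_table`.
#' @examples
#' path <- system.file("extdata", "example_rifampin_synthetic.csv",
#'                     package = "tbpk")
#' head(read_event_table(path))
#' @export
read_event_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  schema_full <- .et_schema_default
  if (!is.null(schema)) schema_full[names(schema)] <- schema
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  missing_cols <- setdiff(schema_full[.et_mandatory], names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "." | x == "", NA, x)))
  lgl <- function(x) num(x) != 0
  tab <- data.frame(
    id = raw[[schema_full["id"]]],
    time = num(raw[[schema_full["time"]]]),
    evid = as.integer(num(raw[[schema_full["evid"]]])),
    amt = num(raw[[schema_full["amt"]]]),
    dv = num(raw[[schema_full["dv"]]]),
    blq = ifelse(is.na(lgl(raw[[schema_full["blq"]]])), FALSE,
                 lgl(raw[[schema_full["blq"]]])),
    lloq = num(raw[[schema_full["lloq"]]]),
    occasion = tolower(ifelse(raw[[schema_full["occasion"]]] %in% c(".", ""),
                              NA, raw[[schema_full["occasion"]]])),
    drug = tolower(raw[[schema_full["drug"]]]),
    stringsAsFactors = FALSE)
  opt_chr <- c(sex = "sex", art_class = "art_class")
  for (nm in c("sex", "art_class")) {
    if (schema_full[nm] %in% names(raw)) {
      tab[[nm]] <- tolower(ifelse(raw[[schema_full[nm]]] %in% c(".", ""),
                                  NA, raw[[schema_full[nm]]]))
    }
  }
  for (nm in c("weight", "height", "age", "albumin", "total_protein")) {
    if (schema_full[nm] %in% names(raw)) tab[[nm]] <- num(raw[[schema_full[nm]]])
  }
  for (nm in c("hiv_positive", "alcohol", "diabetes", "prev_inh")) {
    if (schema_full[nm] %in% names(raw)) tab[[nm]] <- lgl(raw[[schema_full[nm]]])
  }
  validate_event_table(tab)
}

#' Validate an in-memory event table
#'
#' @param tab data frame with canonical event-table columns.
#' @return the validated table (class `tbpk_event_table`); on any violation,
#'   an error of class `tbpk_validation_error` whose message lists each
#'   offending row number and rule.
#' @export
validate_event_table <- function(tab) {
  problems <- character()
  bad <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      problems <<- c(problems,
                     sprintf("row %d: %s", which(rows), msg))
    }
  }
  bad(is.na(tab$time) | tab$time < 0, "time missing or negative")
  for (sid in unique(tab$id)) {
    idx <- which(tab$id == sid)
    if (is.unsorted(tab$time[idx], na.rm = TRUE)) {
      problems <- c(problems,
                    sprintf("subject %s: times not non-decreasing", sid))
    }
  }
  is_obs <- tab$evid == 0
  bad(tab$blq & !is.na(tab$dv), "BLQ record has a numeric concentration")
  bad(tab$blq & is.na(tab$lloq), "BLQ record lacks an LLOQ")
  bad(is_obs & !is.na(tab$amt), "observation record carries a dose amount")
  bad(!is_obs & !is.na(tab$dv), "dose record carries a concentration")
  bad(is_obs & (is.na(tab$occasion) |
                  !tab$occasion %in% c("predose", "intensive")),
      "observation without a valid occasion")
  bad(!tab$evid %in% c(0L, 1L), "EVID must be 0 (observation) or 1 (dose)")
  if (length(problems)) {
    stop(structure(class = c("tbpk_validation_error", "error", "condition"),
                   list(message = paste0("event-table validation failed:\n  ",
                                         paste(problems, collapse = "\n  ")),
                        call = sys.call(-1), problems = problems)))
  }
  class(tab) <- unique(c("tbpk_event_table", class(tab)))
  tab
}

#' Write an event table
#'
#' Writes the comma-separated NONMEM-style dialect read by
#' [read_event_table()]: "." for missing values, BLQ rows with an empty
#' concentration and the LLOQ filled, `MDV = 1` where the concentration is
#' missing on an observation record.
#'
#' @param tab a validated event table.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_event_table <- function(tab, path) {
  tab <- validate_event_table(as.data.frame(tab))
  fmt <- function(x) {
    if (is.logical(x)) x <- as.integer(x)
    out <- as.character(x)
    out[is.na(out)] <- "."
    out
  }
  out <- data.frame(
    ID = fmt(tab$id), TIME = fmt(tab$time), EVID = fmt(tab$evid),
    AMT = fmt(tab$amt), DV = fmt(tab$dv),
    MDV = fmt(as.integer(tab$evid != 0 | is.na(tab$dv))),
    BLQ = fmt(tab$blq), LLOQ = fmt(tab$lloq),
    OCC = fmt(toupper(tab$occasion)), DRUG = fmt(toupper(tab$drug)),
    stringsAsFactors = FALSE, check.names = FALSE)
  opt <- c(sex = "SEX", weight = "WT", height = "HT", hiv_positive = "HIV",
           art_class = "ART", age = "AGE", albumin = "ALB",
           total_protein = "TPROT", alcohol = "ALCOHOL",
           diabetes = "DIABETES", prev_inh = "PREVINH")
  for (nm in names(opt)) {
    if (!is.null(tab[[nm]])) {
      v <- tab[[nm]]
      out[[opt[nm]]] <- fmt(if (nm %in% c("sex", "art_class")) toupper(v) else v)
    }
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Validate an analysis configuration
#'
#' Fills defaults (visual predictive check with n = 500 simulations;
#' importance sampling with n = 20,000; low-Cmax thresholds 8/3/35 mg/L for
#' rifampin/isoniazid/pyrazinamide) and rejects unknown keys and
#' non-positive counts.
#'
#' @param config named list of settings, or a path to a YAML file.
#' @return list of class `tbpk_config` with all defaults applied.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    drug = "rifampin",
    vpc_nsim = 500L,
    vpc_percentiles = c(10, 50, 90),
    vpc_ci = 90,
    is_nsamples = 20000L,
    cmax_thresholds = c(rifampin = 8, isoniazid = 3, pyrazinamide = 35),
    dose_interval = 24,
    seed = 1L,
    covariate_candidates = c("sex", "age", "albumin", "total_protein",
                             "hiv_positive", "cd4_lt200", "art_class",
                             "total_dose", "dose_per_kg"))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(config)] <- config
  for (nm in c("vpc_nsim", "is_nsamples", "dose_interval")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("config '", nm, "' must be a positive count")
    }
  }
  if (any(cfg$vpc_percentiles <= 0 | cfg$vpc_percentiles >= 100)) {
    stop("vpc_percentiles must be in (0, 100)")
  }
  if (cfg$vpc_ci <= 0 || cfg$vpc_ci >= 100) stop("vpc_ci must be in (0, 100)")
  if (any(cfg$cmax_thresholds <= 0)) stop("cmax_thresholds must be positive")
  structure(cfg, class = "tbpk_config")
}
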
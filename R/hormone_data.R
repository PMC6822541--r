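# Domain types and CSV I/O for whale hormone records and posterior
# summary tables.
#
# A hormone dataset is a data.frame with one row per biopsy measurement:
# whale_id, sex ("female"/"male"), hormone ("progesterone"/"testosterone"),
# concentration (ng per g blubber, > 0), date (Date), day_of_year (1-366),
# optional region and stage ("lactating"/"unknown"), and a `replicated`
# flag that is FALSE for original observations (TRUE only for the winter
# copies added by augment_winter_replication()). Extra CSV columns are
# preserved untouched.

DATASET_COLUMNS <- c("whale_id", "sex", "hormone", "concentration",
                     "date", "day_of_year", "region", "stage", "replicated")

norm_sex <- function(x) {
  key <- c(f = "female", female = "female", m = "male", male = "male")
  out <- unname(key[tolower(trimws(as.character(x)))])
  out
}

norm_hormone <- function(x) {
  key <- c(progesterone = "progesterone", p4 = "progesterone",
           testosterone = "testosterone", t = "testosterone")
  unname(key[tolower(trimws(as.character(x)))])
}

day_of_year <- function(date) as.integer(format(date, "%j"))

#' Construct a hormone dataset
#'
#' Validates and assembles biopsy hormone records into a
#' `hormone_dataset` (a data.frame subclass). `day_of_year` is derived
#' from `date` when missing. Concentrations must be strictly positive
#' (the models work on the log scale). In this study's design progesterone
#' is assayed in females and testosterone in males; records violating that
#' pairing raise a warning, not an error.
#'
#' @param whale_id character individual identifiers.
#' @param sex "female"/"male" (also accepts "F"/"M").
#' @param hormone "progesterone"/"testosterone" (also "P4"/"T").
#' @param concentration positive numeric, ng per g blubber.
#' @param date `Date` (or ISO-8601 strings).
#' @param region optional character.
#' @param stage optional, "lactating" or "unknown".
#' @param replicated logical, `FALSE` for original observations.
#' @param provenance free-text origin of the data.
#' @param extra optional data.frame of extra columns carried along.
#' @return A `hormone_dataset`.
#' @export
hormone_dataset <- function(whale_id, sex, hormone, concentration, date,
                            region = NA_character_, stage = "unknown",
                            replicated = FALSE, provenance = "unspecified",
                            extra = NULL) {
  n <- length(whale_id)
  date <- as.Date(date)
  sex <- norm_sex(sex)
  hormone <- norm_hormone(hormone)
  d <- data.frame(whale_id = as.character(whale_id), sex = sex,
                  hormone = hormone,
                  concentration = as.numeric(concentration),
                  date = date, day_of_year = day_of_year(date),
                  region = rep_len(as.character(region), n),
                  stage = rep_len(as.character(stage), n),
                  replicated = rep_len(as.logical(replicated), n),
                  stringsAsFactors = FALSE)
  if (!is.null(extra)) d <- cbind(d, extra)
  validate_hormone_dataset(d)
  attr(d, "provenance") <- provenance
  class(d) <- c("hormone_dataset", "data.frame")
  d
}

validate_hormone_dataset <- function(d) {
  bad <- which(!is.finite(d$concentration) | d$concentration <= 0)
  if (length(bad))
    stop("nonpositive or missing concentration in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyNA(d$sex)) stop("unrecognized sex value(s) in row(s): ",
                         paste(which(is.na(d$sex)), collapse = ", "),
                         call. = FALSE)
  if (anyNA(d$hormone)) stop("unrecognized hormone value(s) in row(s): ",
                             paste(which(is.na(d$hormone)), collapse = ", "),
                             call. = FALSE)
  if (anyNA(d$date)) stop("unparseable date(s) in row(s): ",
                          paste(which(is.na(d$date)), collapse = ", "),
                          call. = FALSE)
  mism <- (d$hormone == "progesterone" & d$sex != "female") |
    (d$hormone == "testosterone" & d$sex != "male")
  if (any(mism))
    warning("hormone/sex pairing differs from the study design ",
            "(progesterone in females, testosterone in males) in row(s): ",
            paste(which(mism), collapse = ", "))
  orig <- d[!d$replicated, , drop = FALSE]
  key <- paste(orig$whale_id, orig$date, orig$hormone)
  if (anyDuplicated(key))
    stop("duplicate whale_id + date among non-replicated records: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  invisible(d)
}

#' @export
print.hormone_dataset <- function(x, ...) {
  cat(sprintf("hormone_dataset: %d records (%d replicated), provenance: %s\n",
              nrow(x), sum(x$replicated), attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read hormone records from CSV
#'
#' Parses a UTF-8, header-row CSV of biopsy hormone measurements into a
#' [hormone_dataset()]. Dates must be ISO-8601 (`YYYY-MM-DD`); day of year
#' is derived from the date. Malformed rows are reported with their row
#' numbers. Columns beyond the schema are preserved as opaque metadata.
#'
#' @param path path to a CSV file.
#' @param schema named character vector mapping the required logical
#'   columns `id`, `sex`, `hormone`, `date`, `concentration` (and optional
#'   `region`, `stage`, `replicated`) to the file's column names. Defaults
#'   to identically named columns.
#' @return A `hormone_dataset`.
#' @export
read_hormone_csv <- function(path,
                             schema = c(id = "whale_id", sex = "sex",
                                        hormone = "hormone", date = "date",
                                        concentration = "concentration")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read as character: "F"/"T" sex codes would otherwise be parsed logical
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  required <- c("id", "sex", "hormone", "date", "concentration")
  miss <- setdiff(required, names(schema))
  if (length(miss))
    stop("schema must map column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(unname(schema), names(raw))
  if (length(absent))
    stop("missing required column(s) in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  get_opt <- function(logical_name, default) {
    if (logical_name %in% names(schema)) raw[[schema[[logical_name]]]]
    else if (logical_name %in% names(raw)) raw[[logical_name]]
    else default
  }
  extra_cols <- setdiff(names(raw), c(unname(schema), DATASET_COLUMNS))
  hormone_dataset(
    whale_id = raw[[schema[["id"]]]],
    sex = raw[[schema[["sex"]]]],
    hormone = raw[[schema[["hormone"]]]],
    concentration = suppressWarnings(as.numeric(raw[[schema[["concentration"]]]])),
    date = raw[[schema[["date"]]]],
    region = get_opt("region", NA_character_),
    stage = get_opt("stage", "unknown"),
    replicated = as.logical(get_opt("replicated", FALSE)),
    provenance = path,
    extra = if (length(extra_cols)) raw[extra_cols] else NULL
  )
}

#' Write hormone records to CSV
#'
#' Inverse of [read_hormone_csv()]: `read_hormone_csv(write_hormone_csv(x))`
#' round-trips all standard fields.
#'
#' @param dataset a `hormone_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hormone_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "hormone_dataset"))
  out <- as.data.frame(dataset)
  out$date <- format(out$date, "%Y-%m-%d")
  # 17 significant digits: doubles round-trip exactly through the file
  out$concentration <- sprintf("%.17g", out$concentration)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a posterior summary table to CSV
#'
#' Emits the posterior-summary layout used for hormone mean tables:
#' columns `parameter, Mean, SD, 2.5%, 25.0%, 50.0%, 75.0%, 97.5%, Rhat,
#' Neff (%)`, one row per parameter.
#'
#' @param summaries a `posterior_summary` data.frame (see
#'   [summarize_posterior()], [bind_summaries()]); must be non-empty.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  if (is.null(summaries) || !nrow(summaries))
    stop("no summaries to write", call. = FALSE)
  cols <- c("parameter", "Mean", "SD", "2.5%", "25.0%", "50.0%", "75.0%",
            "97.5%", "Rhat", "Neff (%)")
  stopifnot(all(cols %in% names(summaries)))
  utils::write.csv(summaries[cols], path, row.names = FALSE)
  invisible(path)
}

#' Assay duplicate measurement
#'
#' Back-calculated concentrations (pg per mL) of one sample measured in
#' replicate on an assay plate, with the dilution applied.
#'
#' @param sample_id sample label.
#' @param replicate_values numeric vector of at least two nonnegative
#'   back-calculated concentrations, pg per mL.
#' @param dilution_factor positive dilution factor applied to the sample.
#' @return An `assay_measurement` object.
#' @export
assay_measurement <- function(sample_id, replicate_values,
                              dilution_factor = 1) {
  replicate_values <- as.numeric(replicate_values)
  if (length(replicate_values) < 2L)
    stop("need at least 2 replicate values", call. = FALSE)
  if (any(!is.finite(replicate_values) | replicate_values < 0))
    stop("replicate values must be finite and >= 0", call. = FALSE)
  stopifnot(is.finite(dilution_factor), dilution_factor > 0)
  structure(list(sample_id = as.character(sample_id),
                 replicate_values = replicate_values,
                 dilution_factor = dilution_factor),
            class = "assay_measurement")
}
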
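# Validate a long observation table and convert it to canonical units:
# columns subject_id, drug, regimen, time_h, conc ((10^3 mg)/ml),
# dose (10^3 mg).  Accepts the raw schema with `concentration`,
# `conc_unit`, `dose_mg` columns.
.validate_obs_table <- function(data, path = "<data>") {
  req <- c("subject_id", "drug", "regimen", "time_h", "concentration",
           "conc_unit", "dose_mg")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(!data$regimen %in% c("single", "combined")))
    stop("'regimen' must be 'single' or 'combined'", call. = FALSE)
  bad_t <- which(!is.finite(data$time_h) | data$time_h < 0)
  if (length(bad_t))
    stop("negative or non-finite time_h at row(s) ",
         paste(utils::head(bad_t, 5L), collapse = ", "), " of ", path,
         call. = FALSE)
  if (any(!is.finite(data$concentration) | data$concentration < 0))
    stop("concentrations must be non-negative and finite", call. = FALSE)
  grp <- interaction(data$subject_id, data$drug, data$regimen,
                     drop = TRUE)
  for (g in split(seq_len(nrow(data)), grp)) {
    tt <- data$time_h[g]
    if (any(diff(tt) <= 0))
      stop("times not strictly increasing within group (subject ",
           data$subject_id[g[1L]], ", drug ", data$drug[g[1L]],
           ", ", data$regimen[g[1L]], ") of ", path, call. = FALSE)
    if (length(unique(data$dose_mg[g])) != 1L)
      stop("dose_mg not constant within group (subject ",
           data$subject_id[g[1L]], ", drug ", data$drug[g[1L]], ")",
           call. = FALSE)
  }
  f <- vapply(as.character(data$conc_unit), .conc_unit_factor,
              numeric(1L))
  out <- data.frame(subject_id = data$subject_id, drug = data$drug,
                    regimen = data$regimen, time_h = data$time_h,
                    conc = data$concentration * f,
                    dose = data$dose_mg / 1000)
  class(out) <- c("pk_observation_table", "data.frame")
  out
}

#' Read a long-format concentration-time observation table
#'
#' Reads a CSV file (or one sheet of an XLSX workbook) with columns
#' `subject_id`, `drug`, `regimen` (`"single"`/`"combined"`),
#' `time_h`, `concentration`, `conc_unit`, `dose_mg`, validates it
#' (non-negative strictly increasing times per subject/drug/regimen
#' group, constant dose within group, known units) and converts to
#' canonical units: concentrations to (10^3 mg)/ml and doses to
#' 10^3 mg.  Column-name differences can be bridged with `col_map`.
#'
#' @param path file path.
#' @param format `"csv"` or `"xlsx"`; inferred from the extension by
#'   default.  Reading XLSX requires the `readxl` package.
#' @param sheet sheet name or index for XLSX input.
#' @param col_map optional named character vector mapping required
#'   column names to the names used in the file, e.g.
#'   `c(time_h = "Time")`.
#' @return A validated data frame of class `pk_observation_table` with
#'   columns `subject_id`, `drug`, `regimen`, `time_h`, `conc`
#'   ((10^3 mg)/ml), `dose` (10^3 mg).
#' @export
read_observations <- function(path, format = c("auto", "csv", "xlsx"),
                              sheet = 1L, col_map = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx"
              else "csv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading xlsx requires the 'readxl' package", call. = FALSE)
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  }
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      i <- match(col_map[[canon]], names(data))
      if (is.na(i))
        stop("col_map: column '", col_map[[canon]], "' not in file",
             call. = FALSE)
      names(data)[i] <- canon
    }
  }
  .validate_obs_table(data, path = path)
}

#' Write fit results or metric tables with provenance
#'
#' Writes a data frame (or a `coupledpk_fit` / `pk_interfit` summary)
#' to CSV or JSON at full numeric precision.  JSON output wraps the
#' payload with a provenance block recording the seed, regularization
#' strength, bounds and solver tolerances of the run, so a result file
#' identifies the configuration that produced it.
#'
#' @param x a data frame, `pk_interfit` or `coupledpk_fit`.
#' @param path output path.
#' @param format `"csv"` or `"json"`; inferred from the extension by
#'   default.
#' @param provenance optional named list merged into the JSON
#'   provenance block.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("auto", "csv", "json"),
                          provenance = list()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  payload <- x
  prov <- provenance
  if (inherits(x, "pk_interfit")) {
    payload <- data.frame(parameter = names(x$W), estimate = unname(x$W))
    prov <- c(list(seed = x$control$seed, lambda = x$lambda,
                   lower = as.list(x$constraints$lower),
                   upper = as.list(x$constraints$upper),
                   r2_x = x$r2_x, r2_y = x$r2_y, aic = x$aic), prov)
  } else if (inherits(x, "coupledpk_fit")) {
    payload <- data.frame(parameter = names(x$W), estimate = unname(x$W),
                          ci_lower = x$W_ci[, "lower"],
                          ci_upper = x$W_ci[, "upper"])
    prov <- c(list(seed = x$control$seed, lambda = x$lambda,
                   r2 = as.list(x$r2), aic = x$aic), prov)
  }
  if (format == "csv") {
    utils::write.csv(payload, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(provenance = prov, results = payload), path,
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
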
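#' Chemistry variable names and units
#'
#' The canonical per-sample chemistry variables and the units in which the
#' package stores them. Note residual sugar is carried in mg/100 mL (not
#' g/L): all published coefficients and the synthetic generator assume these
#' units, and no reader ever rescales a column silently.
#'
#' @return named character vector mapping variable name to unit.
#' @export
chemistry_units <- function() {
  c(alcohol = "% v/v", ph = "pH", malic_acid = "g/L",
    titratable_acidity = "g/L as malic acid", residual_sugar = "mg/100 mL",
    polyphenols = "mg/L", hydroxybenzoic = "mg/L", hydroxycinnamic = "mg/L",
    abs280 = "AU", abs320 = "AU", tannins = "mg/L")
}

chemistry_vars <- function() names(chemistry_units())

#' Load a packaged fixture table
#'
#' The package ships transcriptions of the published per-sample score table
#' (76 ciders scored on the IRF, pH-corrected IRF and NYCA scales plus the
#' trained-panel sensory score), the 38-sample validation rating table
#' (NYCA, sensory and three PLS-model ratings), and the per-variable
#' distribution summaries of the calibration and validation chemistry.
#' Rating labels are normalized to the canonical spellings on load
#' ("semidry" in the source table becomes "semi-dry"); score and label cells
#' are otherwise verbatim transcriptions, including the sensory label of
#' sample KS2 which is stored as printed even though its score of 7.0 falls
#' in the sweet band.
#'
#' @param name one of `"table4"` (scored samples), `"table7"` (validation
#'   ratings), `"table3_calibration"`, `"table3_validation"` (distribution
#'   summaries).
#' @return a data frame; rating columns are ordered factors
#'   (see [dryness_category()]).
#' @examples
#' nrow(load_fixture("table4"))  # 76
#' load_fixture("table7")[1:3, ]
#' @export
load_fixture <- function(name = c("table4", "table7", "table3_calibration",
                                  "table3_validation")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("unknown fixture name: ",
                                            name[1], call. = FALSE))
  file <- switch(name,
    table4 = "table4_scores.csv",
    table7 = "table7_validation_ratings.csv",
    table3_calibration = "table3_calibration.csv",
    table3_validation = "table3_validation.csv")
  path <- fixture_path(file)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  rating_cols <- grep("_rating|rating_", names(x), value = TRUE)
  for (cl in rating_cols) x[[cl]] <- dryness_category(x[[cl]])
  x
}

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "ciderdry")
  if (!nzchar(path)) stop("fixture file not installed: ", file, call. = FALSE)
  path
}

#' MD5 checksums of the packaged fixture transcriptions
#'
#' Used to guard the transcriptions against accidental edits.
#'
#' @return named character vector of MD5 hex digests, one per fixture CSV.
#' @export
fixture_checksums <- function() {
  files <- c(table4 = "table4_scores.csv",
             table7 = "table7_validation_ratings.csv",
             table3_calibration = "table3_calibration.csv",
             table3_validation = "table3_validation.csv")
  sums <- vapply(files, function(f) unname(tools::md5sum(fixture_path(f))), "")
  names(sums) <- names(files)
  sums
}

#' Read and write cider chemistry tables
#'
#' `read_chemistry_csv()` reads an RFC-4180 CSV of per-sample cider
#' chemistry into a validated table. Columns may be renamed through
#' `dialect`, a named character vector mapping canonical names to the names
#' used in the file; units are never converted (the package's unit
#' conventions are those of [chemistry_units()]). The tannin column is
#' optional; all other chemistry columns and `sample_id` are mandatory.
#' `write_chemistry_csv()` writes the table back with full double precision.
#'
#' @param path file path.
#' @param dialect optional named character vector, e.g.
#'   `c(residual_sugar = "RS_mg_100mL")`.
#' @return `read_chemistry_csv()`: data frame with columns `sample_id` plus
#'   the [chemistry_units()] variables (tannins `NA` if absent from the
#'   file).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' chem <- generate_chemistry(synthetic_config(n_samples = 5, seed = 1))
#' write_chemistry_csv(chem, tf)
#' chem2 <- read_chemistry_csv(tf)
#' @export
read_chemistry_csv <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      j <- match(dialect[[canon]], names(x))
      if (!is.na(j)) names(x)[j] <- canon
    }
  }
  mandatory <- c("sample_id", setdiff(chemistry_vars(), "tannins"))
  miss <- setdiff(mandatory, names(x))
  if (length(miss))
    stop("chemistry CSV is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!("tannins" %in% names(x))) x$tannins <- NA_real_
  x <- x[, c("sample_id", chemistry_vars())]
  x$sample_id <- as.character(x$sample_id)
  for (v in chemistry_vars()) x[[v]] <- as.numeric(x[[v]])
  validate_chemistry(x)
  x
}

#' @rdname read_chemistry_csv
#' @param chem a chemistry data frame as returned by `read_chemistry_csv()`
#'   or [generate_chemistry()].
#' @export
write_chemistry_csv <- function(chem, path) {
  validate_chemistry(chem)
  out <- chem[, c("sample_id", intersect(chemistry_vars(), names(chem)))]
  for (v in setdiff(names(out), "sample_id"))
    out[[v]] <- formatC(out[[v]], digits = 15, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_chemistry <- function(chem) {
  stopifnot(is.data.frame(chem), "sample_id" %in% names(chem))
  if (anyDuplicated(chem$sample_id))
    stop("duplicate sample_id in chemistry table: ",
         paste(unique(chem$sample_id[duplicated(chem$sample_id)]),
               collapse = ", "), call. = FALSE)
  for (v in intersect(chemistry_vars(), names(chem))) {
    val <- chem[[v]]
    if (v == "ph") {
      bad <- !is.na(val) & (val <= 0 | val >= 14)
      if (any(bad))
        stop("ph out of (0, 14) for sample(s): ",
             paste(chem$sample_id[bad], collapse = ", "), call. = FALSE)
    } else {
      bad <- !is.na(val) & val < 0
      if (any(bad))
        stop("negative ", v, " for sample(s): ",
             paste(chem$sample_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  invisible(chem)
}
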
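# Core data containers: spectra tables and reference (pH / TSS) tables.
#
# Spectra live in a flat sample x wavelength matrix with the wavelength
# axis stored as numbers (nm), so downstream variable selection can work
# on plain column indices without interpolation.

#' Construct a spectrum set
#'
#' A `spectrum_set` holds a sample x wavelength matrix of NIR readings
#' together with its wavelength axis (nm), an acquisition mode
#' (reflectance fraction in (0, 1] or absorbance) and per-sample
#' metadata (variety, fermentation time in hours, subsample, replicate).
#'
#' @param values numeric matrix, one row per sample, one column per
#'   wavelength.
#' @param wavelengths strictly increasing numeric vector of nm values,
#'   one per column of `values`.
#' @param mode `"reflectance"` or `"absorbance"`. Reflectance values
#'   must lie in (0, 1].
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to the rownames of `values`.
#' @param metadata optional data.frame of per-sample metadata with one
#'   row per sample (columns such as `variety`, `time_h`, `subsample`,
#'   `replicate`).
#' @return an object of class `spectrum_set`.
#' @export
spectrum_set <- function(values, wavelengths,
                         mode = c("reflectance", "absorbance"),
                         sample_ids = rownames(values),
                         metadata = NULL) {
  mode <- match.arg(mode)
  values <- check_finite_matrix(values, "values")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(values)) {
    stop("length(wavelengths) must equal ncol(values)", call. = FALSE)
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (mode == "reflectance" && (any(values <= 0) || any(values > 1))) {
    stop("reflectance values must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%03d", seq_len(nrow(values)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("sample_ids length must equal nrow(values)", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != nrow(values)) {
      stop("metadata must have one row per sample", call. = FALSE)
    }
  }
  rownames(values) <- sample_ids
  colnames(values) <- format(wavelengths, trim = TRUE, scientific = FALSE)
  structure(
    list(values = values, wavelengths = wavelengths, mode = mode,
         sample_ids = sample_ids, metadata = metadata),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d wavelengths (%.0f-%.0f nm), mode=%s\n",
              nrow(x$values), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), x$mode))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$values)

# metadata columns recognised in the CSV dialect, in canonical order
.meta_cols <- c("sample_id", "variety", "time_h", "subsample", "replicate")

#' Read a spectra table from CSV
#'
#' Expects a comma-delimited UTF-8 table with one header row. Leading
#' columns hold `sample_id` and optional metadata (`variety`, `time_h`,
#' `subsample`, `replicate`); every remaining column name must parse as
#' a wavelength in nm, and the wavelengths must be strictly increasing.
#'
#' @param path file path.
#' @param mode acquisition mode of the stored values, `"reflectance"`
#'   or `"absorbance"`.
#' @return a [spectrum_set].
#' @export
read_spectra <- function(path, mode = c("reflectance", "absorbance")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_present <- intersect(.meta_cols, names(df))
  if (!("sample_id" %in% meta_present)) {
    stop("spectra file must have a sample_id column", call. = FALSE)
  }
  wl_cols <- setdiff(names(df), meta_present)
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) {
    stop(sprintf("non-numeric wavelength header: %s",
                 paste(utils::head(wl_cols[is.na(wl)], 3), collapse = ", ")),
         call. = FALSE)
  }
  if (length(wl) > 1 && any(diff(wl) <= 0)) {
    stop("wavelength header is not strictly increasing", call. = FALSE)
  }
  vals <- as.matrix(df[, wl_cols, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    stop("non-numeric or missing cell in spectra table", call. = FALSE)
  }
  meta <- df[, setdiff(meta_present, "sample_id"), drop = FALSE]
  if (ncol(meta) == 0) meta <- NULL
  spectrum_set(vals, wl, mode = mode, sample_ids = df$sample_id,
               metadata = meta)
}

#' Write a spectra table to CSV
#'
#' Inverse of [read_spectra()]: values and wavelengths round-trip to
#' full printed precision (15 significant digits).
#'
#' @param s a [spectrum_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path) {
  stopifnot(inherits(s, "spectrum_set"))
  df <- data.frame(sample_id = s$sample_ids, stringsAsFactors = FALSE)
  if (!is.null(s$metadata)) df <- cbind(df, s$metadata)
  vals <- as.data.frame(s$values)
  names(vals) <- format(s$wavelengths, trim = TRUE, scientific = FALSE,
                        digits = 15)
  df <- cbind(df, vals)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a reference table of response values
#'
#' Holds one laboratory response (pH or TSS in degrees Brix) per sample,
#' keyed by sample id, for joining against a [spectrum_set].
#'
#' @param sample_ids character vector of unique sample ids.
#' @param y numeric response vector, finite; pH must lie in (0, 14),
#'   TSS must be non-negative.
#' @param response `"pH"` or `"TSS"`.
#' @return an object of class `reference_table`.
#' @export
reference_table <- function(sample_ids, y, response = c("pH", "TSS")) {
  response <- match.arg(response)
  sample_ids <- as.character(sample_ids)
  y <- as.numeric(y)
  if (length(sample_ids) != length(y)) {
    stop("sample_ids and y must have the same length", call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  if (response == "pH" && (any(y <= 0) || any(y >= 14))) {
    stop("pH values must lie in (0, 14)", call. = FALSE)
  }
  if (response == "TSS" && any(y < 0)) {
    stop("TSS values must be non-negative", call. = FALSE)
  }
  structure(
    list(sample_ids = sample_ids, y = y, response = response,
         units = if (response == "TSS") "°Brix" else ""),
    class = "reference_table"
  )
}

#' Read a reference table from CSV
#'
#' @param path CSV with columns `sample_id` and `value`.
#' @param response `"pH"` or `"TSS"`.
#' @return a [reference_table].
#' @export
read_reference <- function(path, response = c("pH", "TSS")) {
  response <- match.arg(response)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "value") %in% names(df))) {
    stop("reference file must have sample_id and value columns", call. = FALSE)
  }
  reference_table(df$sample_id, df$value, response)
}

#' Write a reference table to CSV
#'
#' @param ref a [reference_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference_table"))
  utils::write.csv(
    data.frame(sample_id = ref$sample_ids, value = ref$y),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Join spectra with reference values
#'
#' Aligns a reference table to the row order of a spectrum set by
#' sample id. The spectra order is preserved; the reference order is
#' irrelevant. Every spectrum id must occur exactly once in the
#' reference table.
#'
#' @param spectra a [spectrum_set].
#' @param refs a [reference_table].
#' @return an object of class `nir_dataset`: list with the spectra, the
#'   aligned response vector `y`, the response name and the sample ids.
#' @export
join_dataset <- function(spectra, refs) {
  stopifnot(inherits(spectra, "spectrum_set"), inherits(refs, "reference_table"))
  dup <- refs$sample_ids[duplicated(refs$sample_ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate sample_id in reference table: %s", dup[1]),
         call. = FALSE)
  }
  idx <- match(spectra$sample_ids, refs$sample_ids)
  if (anyNA(idx)) {
    missing_id <- spectra$sample_ids[which(is.na(idx))[1]]
    stop(sprintf("sample_id not found in reference table: %s", missing_id),
         call. = FALSE)
  }
  structure(
    list(spectra = spectra, y = refs$y[idx], response = refs$response,
         sample_ids = spectra$sample_ids),
    class = "nir_dataset"
  )
}

#' @export
print.nir_dataset <- function(x, ...) {
  cat(sprintf("<nir_dataset> %d samples, %d wavelengths, response=%s\n",
              nrow(x$spectra$values), length(x$spectra$wavelengths),
              x$response))
  invisible(x)
}
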
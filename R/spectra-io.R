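#' Read and write wide-format spectra CSV files
#'
#' The on-disk format is a plain CSV: first column `sample_id`, optional
#' metadata columns, and one column per wavenumber whose header is the
#' wavenumber in cm^-1. `read_spectra()` validates that the grid is strictly
#' monotone, ids are unique and all absorbance values are finite;
#' `write_spectra()` writes with enough digits that a write/read round trip
#' is lossless to at least 12 significant digits.
#'
#' @param path file path of a CSV in the wide layout.
#' @return `read_spectra()` returns a spectra tibble (see [spectra_tbl()]).
#' @examples
#' sp <- spectra_tbl(c("a", "b"), rbind(1:3, 4:6), grid = c(12, 8, 4))
#' tmp <- tempfile(fileext = ".csv")
#' write_spectra(sp, tmp)
#' read_spectra(tmp)
#' @export
read_spectra <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  if (!"sample_id" %in% names(df)) {
    abort("spectra CSV must have a `sample_id` first column")
  }
  df$sample_id <- as.character(df$sample_id)
  cols <- spectral_cols(df)
  if (length(cols) == 0) {
    abort("no numeric wavenumber headers found in spectra CSV")
  }
  grid <- as.numeric(cols)
  if (anyDuplicated(grid)) {
    dup <- cols[duplicated(grid)][1]
    abort(paste0("duplicated wavenumber column in header: ", dup))
  }
  check_grid(grid)
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("duplicate sample ids in ", path, ": ",
                 df$sample_id[duplicated(df$sample_id)][1]))
  }
  m <- as.matrix(df[, cols, drop = FALSE])
  if (!is.numeric(m) || !all(is.finite(m))) {
    bad <- cols[!apply(m, 2, function(x) is.numeric(x) && all(is.finite(x)))][1]
    abort(paste0("non-numeric or non-finite absorbance values in column ", bad))
  }
  meta <- df[, setdiff(names(df), c("sample_id", cols)), drop = FALSE]
  spectra_tbl(df$sample_id, m, grid, meta = meta)
}

#' @rdname read_spectra
#' @param spectra a spectra tibble.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(is.data.frame(spectra))
  # readr writes doubles with a round-trippable "shortest representation"
  readr::write_csv(spectra, path, progress = FALSE)
  invisible(path)
}

#' Convert between wavenumber (cm^-1) and wavelength (nm)
#'
#' NIR literature quotes band positions both in nm and in cm^-1; the two are
#' reciprocal: lambda\[nm\] = 1e7 / nu\[cm^-1\]. Both functions are their own
#' inverse under composition.
#'
#' @param wn wavenumber(s) in cm^-1, strictly positive.
#' @param nm wavelength(s) in nm, strictly positive.
#' @return numeric vector of converted values (full precision; round for
#'   display, e.g. 950 nm -> 10526 cm^-1).
#' @examples
#' wn_to_nm(4000)          # 2500 nm
#' round(nm_to_wn(950))    # 10526 cm^-1
#' @export
wn_to_nm <- function(wn) {
  if (!all(is.finite(wn)) || any(wn <= 0)) {
    abort("wavenumber must be positive and finite")
  }
  1e7 / wn
}

#' @rdname wn_to_nm
#' @export
nm_to_wn <- function(nm) {
  if (!all(is.finite(nm)) || any(nm <= 0)) {
    abort("wavelength must be positive and finite")
  }
  1e7 / nm
}

#' Average replicate spectra
#'
#' Instruments scan each berry several times (different berry faces); the
#' mean spectrum represents the sample. Rows are grouped by a metadata key
#' (typically `berry_id`) and averaged arithmetically. Metadata columns that
#' are constant within every group are kept; varying ones (e.g. `face`) are
#' dropped.
#'
#' @param spectra a spectra tibble.
#' @param group_key name of the metadata column to group by.
#' @return a spectra tibble with one row per group; `sample_id` becomes the
#'   group key value.
#' @export
average_replicates <- function(spectra, group_key = "berry_id") {
  if (is.null(group_key) || !nzchar(group_key)) {
    abort("`group_key` must be a non-empty column name")
  }
  if (!group_key %in% names(spectra)) {
    abort(paste0("grouping column `", group_key, "` not found"))
  }
  keys <- as.character(spectra[[group_key]])
  if (anyNA(keys) || any(!nzchar(keys))) {
    abort("grouping key has empty values")
  }
  m <- spectra_matrix(spectra)
  grid <- spectra_grid(spectra)
  ukeys <- unique(keys)
  avg <- rowsum(m, group = factor(keys, levels = ukeys)) /
    as.vector(table(factor(keys, levels = ukeys)))

  meta <- spectra_meta(spectra)
  meta$sample_id <- NULL
  keep <- names(meta)[vapply(names(meta), function(nm) {
    all(tapply(meta[[nm]], keys, function(v) length(unique(v)) == 1))
  }, logical(1))]
  meta_first <- meta[match(ukeys, keys), keep, drop = FALSE]
  spectra_tbl(ukeys, avg, grid, meta = meta_first)
}
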
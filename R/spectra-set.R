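#' Spectra tables
#'
#' Spectra travel through the package as ordinary wide tibbles: a `sample_id`
#' column, any number of metadata columns (`block`, `bag`, `berry_id`,
#' `face`, ...), and one numeric column per grid point whose name is the
#' wavenumber in cm^-1 (e.g. `"12000"`, `"11992"`, ...). This mirrors the
#' on-disk CSV layout and keeps every dplyr verb available; the helpers here
#' move between that layout and the sample-by-wavenumber matrix the numerical
#' routines use.
#'
#' The wavenumber grid must be strictly monotone. FT-NIR instruments report
#' descending cm^-1 and that is the convention of the synthetic generator,
#' but ascending grids are accepted everywhere.
#'
#' @param ids character vector of unique sample identifiers.
#' @param absorbance numeric matrix, rows = samples, columns = grid points.
#' @param grid numeric vector of wavenumbers (cm^-1), strictly monotone.
#' @param meta optional data frame / tibble of per-sample metadata
#'   (row-aligned with `ids`).
#'
#' @return `spectra_tbl()` returns a tibble with columns
#'   `sample_id`, metadata, then the spectral columns in grid order.
#' @examples
#' sp <- spectra_tbl(c("a", "b"), rbind(1:3, 4:6), grid = c(12, 8, 4))
#' spectra_grid(sp)
#' spectra_matrix(sp)
#' @export
spectra_tbl <- function(ids, absorbance, grid, meta = NULL) {
  absorbance <- as.matrix(absorbance)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    abort("sample ids must be unique")
  }
  if (nrow(absorbance) != length(ids)) {
    abort("row count of `absorbance` must equal the number of sample ids")
  }
  if (ncol(absorbance) != length(grid)) {
    abort("column count of `absorbance` must equal the grid length")
  }
  check_grid(grid)
  if (!all(is.finite(absorbance))) {
    abort("absorbance values must all be finite")
  }
  colnames(absorbance) <- format_wn(grid)
  out <- tibble::tibble(sample_id = ids)
  if (!is.null(meta)) {
    meta <- tibble::as_tibble(meta)
    if (nrow(meta) != length(ids)) {
      abort("`meta` must have one row per sample")
    }
    out <- dplyr::bind_cols(out, meta)
  }
  dplyr::bind_cols(out, tibble::as_tibble(absorbance))
}

format_wn <- function(grid) {
  # full precision, no scientific notation, so names round-trip through CSV
  format(grid, trim = TRUE, scientific = FALSE, digits = 12)
}

check_grid <- function(grid) {
  if (length(grid) < 1 || !is.numeric(grid) || !all(is.finite(grid))) {
    abort("wavenumber grid must be a finite numeric vector")
  }
  if (length(grid) > 1) {
    d <- diff(grid)
    if (!(all(d > 0) || all(d < 0))) {
      abort("wavenumber grid must be strictly monotone")
    }
  }
  invisible(grid)
}

#' @rdname spectra_tbl
#' @param spectra a spectra tibble as produced by [spectra_tbl()].
#' @export
spectral_cols <- function(spectra) {
  nm <- names(spectra)
  nm <- nm[nm != "sample_id"]            # keep duplicates visible to callers
  suppressWarnings(num <- as.numeric(nm))
  nm[!is.na(num)]
}

#' @rdname spectra_tbl
#' @export
spectra_grid <- function(spectra) {
  as.numeric(spectral_cols(spectra))
}

#' @rdname spectra_tbl
#' @export
spectra_matrix <- function(spectra) {
  cols <- spectral_cols(spectra)
  if (length(cols) == 0) {
    abort("no spectral (numeric-named) columns found")
  }
  m <- as.matrix(spectra[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- spectra$sample_id
  m
}

#' @rdname spectra_tbl
#' @export
spectra_meta <- function(spectra) {
  spectra[, setdiff(names(spectra), spectral_cols(spectra)), drop = FALSE]
}

#' Replace the spectral block of a spectra tibble
#'
#' Keeps `sample_id` and metadata, replaces the spectral columns with a new
#' matrix on a (possibly new) grid. Used by every transform so metadata is
#' never lost.
#'
#' @inheritParams spectral_cols
#' @param m numeric matrix, one row per sample of `spectra`.
#' @param grid wavenumbers for the columns of `m`; defaults to the grid of
#'   `spectra`.
#' @return a spectra tibble.
#' @keywords internal
#' @export
set_spectra_matrix <- function(spectra, m, grid = spectra_grid(spectra)) {
  m <- as.matrix(m)
  if (nrow(m) != nrow(spectra)) {
    abort("replacement matrix must keep the row count")
  }
  meta <- spectra_meta(spectra)
  spectra_tbl(spectra$sample_id, m, grid,
              meta = meta[, setdiff(names(meta), "sample_id"), drop = FALSE])
}
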
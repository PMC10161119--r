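#' Write / read a voxel grid container
#'
#' Compact container for phantoms and dose grids: a flat little-endian
#' float64 binary file of the array values (column-major) plus a JSON
#' geometry sidecar (`<path>.json`) carrying origin, spacing, dimensions
#' and named content.
#'
#' @param values 3-D numeric array.
#' @param origin_mm,spacing_mm Grid geometry (length-3).
#' @param path Output path for the binary payload; the sidecar is written
#'   to `paste0(path, ".json")`.
#' @param content Free-text content tag (e.g. "rsp", "dose_cGy",
#'   "mask:CTV").
#' @return `write_grid` returns `path` invisibly. `read_grid` returns a
#'   list `values`, `origin_mm`, `spacing_mm`, `dim_vox`, `content`.
#' @export
write_grid <- function(values, origin_mm, spacing_mm, path, content = "grid") {
  stopifnot(length(dim(values)) == 3)
  con <- file(path, "wb")
  writeBin(as.vector(as.numeric(values)), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(format = "spotrobust-grid-v1", content = content,
         origin_mm = origin_mm, spacing_mm = spacing_mm,
         dim_vox = dim(values)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "spotrobust-grid-v1")) {
    abort("not a spotrobust grid container")
  }
  dm <- as.integer(meta$dim_vox)
  con <- file(path, "rb")
  v <- readBin(con, "numeric", n = prod(dm), size = 8, endian = "little")
  close(con)
  list(values = array(v, dim = dm), origin_mm = as.numeric(meta$origin_mm),
       spacing_mm = as.numeric(meta$spacing_mm), dim_vox = dm,
       content = meta$content)
}
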
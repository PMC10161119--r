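#' Specify a voxel phantom with geometric structures
#'
#' A phantom is a regular voxel grid carrying relative stopping power (RSP)
#' plus named structure masks (CTV, organs at risk) rasterized from
#' geometric primitives. It stands in for a planning CT with contoured
#' regions of interest.
#'
#' @param origin_mm Numeric length-3: patient-axes (RL, IS, PA) coordinates
#'   of the centre of voxel (1,1,1), mm.
#' @param spacing_mm Numeric length-3 voxel spacing, mm; all positive.
#' @param dim_vox Integer length-3 grid dimensions.
#' @param background_rsp Relative stopping power outside any region
#'   (water = 1).
#' @param structures A list of structure definitions built with
#'   [struct_sphere()] / [struct_box()]; names are taken from the elements.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(dim_vox = c(40, 40, 40), spacing_mm = c(2, 2, 2),
#'                      structures = list(struct_sphere("CTV", c(0, 0, 0), 15)))
phantom_spec <- function(origin_mm = NULL, spacing_mm = c(2, 2, 2),
                         dim_vox = c(50, 50, 50), background_rsp = 1,
                         structures = list()) {
  stopifnot(length(spacing_mm) == 3, all(spacing_mm > 0),
            length(dim_vox) == 3, all(dim_vox >= 1), background_rsp > 0)
  dim_vox <- as.integer(dim_vox)
  if (is.null(origin_mm)) {
    # centre the grid on the isocenter (0,0,0)
    origin_mm <- -(dim_vox - 1) * spacing_mm / 2
  }
  nm <- vapply(structures, function(s) s$name, character(1))
  if (anyDuplicated(nm)) abort("duplicate structure names in phantom spec")
  names(structures) <- nm
  structure(list(origin_mm = origin_mm, spacing_mm = spacing_mm,
                 dim_vox = dim_vox, background_rsp = background_rsp,
                 structures = structures),
            class = "phantom_spec")
}

#' Geometric structure primitives
#'
#' @param name Structure name (e.g. "CTV", "OAR_cord").
#' @param center_mm Length-3 centre in patient axes, mm.
#' @param radius_mm Sphere radius, mm.
#' @param rsp Relative stopping power inside the structure; `NA` leaves the
#'   background value.
#' @return A structure definition usable in [phantom_spec()].
#' @export
struct_sphere <- function(name, center_mm, radius_mm, rsp = NA_real_) {
  stopifnot(length(center_mm) == 3, radius_mm > 0)
  list(name = name, type = "sphere", center_mm = center_mm,
       radius_mm = radius_mm, rsp = rsp)
}

#' @rdname struct_sphere
#' @param half_mm Length-3 box half-widths, mm.
#' @export
struct_box <- function(name, center_mm, half_mm, rsp = NA_real_) {
  stopifnot(length(center_mm) == 3, length(half_mm) == 3, all(half_mm > 0))
  list(name = name, type = "box", center_mm = center_mm,
       half_mm = half_mm, rsp = rsp)
}

#' Rasterize a phantom specification
#'
#' Builds the RSP grid and one boolean mask per structure on identical
#' geometry. Deterministic: no randomness is involved.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: geometry, `rsp` 3-D array, named
#'   list `masks` of logical arrays, and a tibble `volumes` with each
#'   structure's volume in cc.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$dim_vox
  ax <- lapply(1:3, function(a) spec$origin_mm[a] + (seq_len(dm[a]) - 1) * spec$spacing_mm[a])
  lo <- spec$origin_mm - spec$spacing_mm / 2
  hi <- spec$origin_mm + (dm - 1) * spec$spacing_mm + spec$spacing_mm / 2
  # voxel centre coordinate arrays
  X <- array(rep(ax[[1]], times = dm[2] * dm[3]), dim = dm)
  Y <- array(rep(rep(ax[[2]], each = dm[1]), times = dm[3]), dim = dm)
  Z <- array(rep(ax[[3]], each = dm[1] * dm[2]), dim = dm)
  rsp <- array(spec$background_rsp, dim = dm)
  masks <- list()
  for (s in spec$structures) {
    if (s$type == "sphere") {
      if (any(s$center_mm - s$radius_mm < lo) ||
          any(s$center_mm + s$radius_mm > hi)) {
        abort(sprintf("structure '%s' extends outside the phantom grid", s$name))
      }
      m <- (X - s$center_mm[1])^2 + (Y - s$center_mm[2])^2 +
        (Z - s$center_mm[3])^2 <= s$radius_mm^2
    } else {
      if (any(s$center_mm - s$half_mm < lo) ||
          any(s$center_mm + s$half_mm > hi)) {
        abort(sprintf("structure '%s' extends outside the phantom grid", s$name))
      }
      m <- abs(X - s$center_mm[1]) <= s$half_mm[1] &
        abs(Y - s$center_mm[2]) <= s$half_mm[2] &
        abs(Z - s$center_mm[3]) <= s$half_mm[3]
    }
    if (!is.na(s$rsp)) rsp[m] <- s$rsp
    masks[[s$name]] <- m
  }
  vox_cc <- prod(spec$spacing_mm) / 1000
  volumes <- tibble(
    structure = names(masks) %||% character(0),
    n_voxels = unname(vapply(masks, sum, integer(1))),
    volume_cc = unname(vapply(masks, sum, integer(1))) * vox_cc)
  structure(list(origin_mm = spec$origin_mm, spacing_mm = spec$spacing_mm,
                 dim_vox = dm, rsp = rsp, masks = masks, volumes = volumes,
                 voxel_cc = vox_cc),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d x %d voxels at %g x %g x %g mm\n",
              x$dim_vox[1], x$dim_vox[2], x$dim_vox[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  if (nrow(x$volumes)) print(x$volumes)
  invisible(x)
}

# Voxel-centre coordinate matrix (n_voxels x 3), array order = R column-major.
voxel_coords <- function(phantom) {
  dm <- phantom$dim_vox
  ax <- lapply(1:3, function(a) phantom$origin_mm[a] + (seq_len(dm[a]) - 1) * phantom$spacing_mm[a])
  cbind(rep(ax[[1]], times = dm[2] * dm[3]),
        rep(rep(ax[[2]], each = dm[1]), times = dm[3]),
        rep(ax[[3]], each = dm[1] * dm[2]))
}

# Named mask lookup with a helpful error (e.g. missing CTV).
get_mask <- function(phantom, name) {
  m <- phantom$masks[[name]]
  if (is.null(m)) {
    abort(sprintf("structure '%s' not found in phantom (has: %s)", name,
                  paste(names(phantom$masks), collapse = ", ")))
  }
  m
}
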
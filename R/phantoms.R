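#' Phantom specifications for simulated row-column ultrasound scenes
#'
#' A phantom is described geometrically (in mm, on an x--z slice through the
#' y = 0 plane) and rasterized onto a regular lattice on demand. Matrix rows
#' run along the axial (depth, z) direction, columns along the lateral
#' (azimuth, x) direction; physical positions refer to voxel centres.
#'
#' @param grid_shape integer vector `c(nz, nx)`: voxels along depth/lateral.
#' @param voxel_pitch numeric vector `c(dz, dx)` in mm per voxel.
#' @param origin numeric `c(z0, x0)`: mm position of the first voxel centre.
#' @param features list of geometric primitives; each a list with `type`
#'   (`"sphere"`, `"box"` or `"point"`), geometry in mm and an
#'   `amplitude_ratio` (> 0) relative to background.
#' @param background background reflectivity (default 1).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_pitch, origin = c(0, 0),
                         features = list(), background = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop_arg("grid_shape must be two positive integers c(nz, nx)")
  if (length(voxel_pitch) != 2L || any(voxel_pitch <= 0))
    stop_arg("voxel_pitch must be two positive values c(dz, dx) in mm")
  spec <- structure(
    list(grid_shape = grid_shape, voxel_pitch = as.numeric(voxel_pitch),
         origin = as.numeric(origin), features = features,
         background = background),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

grid_extent <- function(spec) {
  # inclusive voxel-centre extent, rows = c(min, max), per axis (z then x)
  z <- spec$origin[1] + c(0, (spec$grid_shape[1] - 1L) * spec$voxel_pitch[1])
  x <- spec$origin[2] + c(0, (spec$grid_shape[2] - 1L) * spec$voxel_pitch[2])
  list(z = z, x = x)
}

validate_phantom_spec <- function(spec) {
  ext <- grid_extent(spec)
  for (k in seq_along(spec$features)) {
    f <- spec$features[[k]]
    nm <- f$name %||% paste0("feature ", k, " (", f$type, ")")
    if (is.null(f$amplitude_ratio) || f$amplitude_ratio <= 0)
      stop_arg("geometry error: ", nm, " has non-positive amplitude_ratio")
    bb <- feature_bbox(f)
    inside <- bb$z[1] >= ext$z[1] - 1e-9 && bb$z[2] <= ext$z[2] + 1e-9 &&
      bb$x[1] >= ext$x[1] - 1e-9 && bb$x[2] <= ext$x[2] + 1e-9
    if (!inside)
      stop_arg("geometry error: ", nm, " lies outside the grid extent (z ",
               ext$z[1], "..", ext$z[2], " mm, x ", ext$x[1], "..",
               ext$x[2], " mm)")
  }
  invisible(spec)
}

feature_bbox <- function(f) {
  switch(f$type,
    sphere = {
      r <- f$diameter / 2
      list(z = f$center[["z"]] + c(-r, r), x = f$center[["x"]] + c(-r, r))
    },
    box = list(z = f$corner[["z"]] + c(0, f$extent[["z"]]),
               x = f$corner[["x"]] + c(0, f$extent[["x"]])),
    point = list(z = rep(f$position[["z"]], 2),
                 x = rep(f$position[["x"]], 2)),
    stop_arg("unknown feature type: ", f$type))
}

#' Four-cyst resolution phantom
#'
#' Four spherical cysts at depths 10, 20, 30 and 40 mm with lateral offsets
#' 0, 0, 2.5 and 5 mm and diameters 6, 4, 2 and 2 mm, each ten times the
#' background reflectivity; the deepest two are placed off the centre axis to
#' exercise off-axis behaviour.
#'
#' @inheritParams phantom_spec
#' @param origin mm position of the first voxel centre (depth, lateral).
#' @return A `phantom_spec`.
#' @export
make_cyst_phantom <- function(grid_shape = NULL,
                              voxel_pitch = c(0.05, 0.1),
                              origin = c(0, -10)) {
  if (is.null(grid_shape))
    grid_shape <- c(floor(50 / voxel_pitch[1]) + 1L,
                    floor(20 / voxel_pitch[2]) + 1L)
  depths <- c(10, 20, 30, 40)
  offsets <- c(0, 0, 2.5, 5)
  diameters <- c(6, 4, 2, 2)
  feats <- Map(function(z, x, d, i) {
    list(type = "sphere", center = c(x = x, z = z), diameter = d,
         amplitude_ratio = 10, name = paste0("cyst", i))
  }, depths, offsets, diameters, seq_len(4L))
  phantom_spec(grid_shape, voxel_pitch, origin, feats)
}

#' L-shape phantom
#'
#' Three adjoining 6 mm x 6 mm squares forming an "L", at ten times the
#' background reflectivity. The placement is not pinned down by the source
#' geometry, so it is configurable; the default centres the 12 mm x 12 mm
#' bounding box at 25 mm depth on the centre axis.
#'
#' @inheritParams make_cyst_phantom
#' @param center_depth,center_x mm centre of the L's bounding box.
#' @return A `phantom_spec`.
#' @export
make_lshape_phantom <- function(grid_shape = NULL,
                                voxel_pitch = c(0.05, 0.1),
                                origin = c(0, -10),
                                center_depth = 25, center_x = 0) {
  if (is.null(grid_shape))
    grid_shape <- c(floor(50 / voxel_pitch[1]) + 1L,
                    floor(20 / voxel_pitch[2]) + 1L)
  z0 <- center_depth - 6
  x0 <- center_x - 6
  sq <- function(cx, cz, i)
    list(type = "box", corner = c(x = cx, z = cz), extent = c(x = 6, z = 6),
         amplitude_ratio = 10, name = paste0("square", i))
  feats <- list(sq(x0, z0, 1L),        # top of the vertical leg
                sq(x0, z0 + 6, 2L),    # bottom of the vertical leg
                sq(x0 + 6, z0 + 6, 3L))# foot, to the right
  phantom_spec(grid_shape, voxel_pitch, origin, feats)
}

#' Three-point axial-resolution phantom
#'
#' Point targets at (x, z) = (0, 39.5), (0, 40) and (0, 40.25) mm, used to
#' probe how well close scatterers are resolved. The axial pitch must be fine
#' enough (<= 0.25 mm) for the two deepest points to occupy distinct voxels.
#'
#' @inheritParams make_cyst_phantom
#' @param amplitude_ratio reflectivity of each point target relative to
#'   background. Point targets stand in for strong specular reflectors
#'   (wire targets), so the default is well above the 10x used for cysts.
#' @return A `phantom_spec`.
#' @export
make_point_phantom <- function(grid_shape = NULL,
                               voxel_pitch = c(0.05, 0.1),
                               origin = c(0, -10),
                               amplitude_ratio = 100) {
  if (is.null(grid_shape))
    grid_shape <- c(floor(50 / voxel_pitch[1]) + 1L,
                    floor(20 / voxel_pitch[2]) + 1L)
  zs <- c(39.5, 40, 40.25)
  feats <- lapply(seq_along(zs), function(i)
    list(type = "point", position = c(x = 0, z = zs[i]),
         amplitude_ratio = amplitude_ratio, name = paste0("point", i)))
  spec <- phantom_spec(grid_shape, voxel_pitch, origin, feats)
  iz <- vapply(zs, function(z) mm_to_index(z, origin[1], voxel_pitch[1],
                                           grid_shape[1]), 0L)
  if (anyDuplicated(iz))
    stop_arg("resolution error: axial pitch ", voxel_pitch[1],
             " mm cannot separate point targets at z = ",
             paste(zs, collapse = ", "), " mm")
  spec
}

mm_to_index <- function(pos, origin, pitch, n) {
  i <- as.integer(round((pos - origin) / pitch)) + 1L
  if (i < 1L || i > n)
    stop_arg("geometry error: position ", pos, " mm outside the grid")
  i
}

index_mm <- function(i, origin, pitch) origin + (i - 1) * pitch

#' Rasterize a phantom onto its lattice
#'
#' A voxel belongs to a sphere or box feature iff its centre lies at distance
#' <= radius (closed boundary); point features occupy the single nearest
#' voxel. Where features overlap, the largest amplitude ratio wins (bright
#' inclusions do not add).
#'
#' @param spec a `phantom_spec`.
#' @return A `reflectivity_image`: list with `values` (nz x nx matrix, rows
#'   axial), `pitch` and `origin` (both `c(z, x)` mm).
#' @export
rasterize_phantom <- function(spec) {
  nz <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  zc <- index_mm(seq_len(nz), spec$origin[1], spec$voxel_pitch[1])
  xc <- index_mm(seq_len(nx), spec$origin[2], spec$voxel_pitch[2])
  ratio <- matrix(NA_real_, nz, nx)
  for (f in spec$features) {
    m <- switch(f$type,
      sphere = {
        dz2 <- (zc - f$center[["z"]])^2
        dx2 <- (xc - f$center[["x"]])^2
        outer(dz2, dx2, `+`) <= (f$diameter / 2)^2 + 1e-12
      },
      box = {
        inz <- zc >= f$corner[["z"]] - 1e-12 &
          zc <= f$corner[["z"]] + f$extent[["z"]] + 1e-12
        inx <- xc >= f$corner[["x"]] - 1e-12 &
          xc <= f$corner[["x"]] + f$extent[["x"]] + 1e-12
        outer(inz, inx, `&`)
      },
      point = {
        m <- matrix(FALSE, nz, nx)
        m[mm_to_index(f$position[["z"]], spec$origin[1], spec$voxel_pitch[1], nz),
          mm_to_index(f$position[["x"]], spec$origin[2], spec$voxel_pitch[2], nx)] <- TRUE
        m
      })
    ratio[m] <- pmax(ratio[m], f$amplitude_ratio, na.rm = TRUE)
  }
  values <- matrix(spec$background, nz, nx)
  values[!is.na(ratio)] <- spec$background * ratio[!is.na(ratio)]
  reflectivity_image(values, spec$voxel_pitch, spec$origin)
}

#' @rdname rasterize_phantom
#' @param values nonnegative matrix of relative reflectivity (rows axial).
#' @param pitch,origin `c(z, x)` mm.
#' @export
reflectivity_image <- function(values, pitch, origin = c(0, 0)) {
  if (!is.matrix(values) || any(!is.finite(values)) || any(values < 0))
    stop_arg("reflectivity values must be a finite nonnegative matrix")
  structure(list(values = values, pitch = as.numeric(pitch),
                 origin = as.numeric(origin)),
            class = "reflectivity_image")
}

#' Reflectivity (amplitude ratio times background) at a physical position
#'
#' @param spec a `phantom_spec`.
#' @param x,z lateral / axial position in mm.
#' @export
phantom_value_at <- function(spec, x, z) {
  img <- rasterize_phantom(spec)
  iz <- mm_to_index(z, spec$origin[1], spec$voxel_pitch[1], spec$grid_shape[1])
  ix <- mm_to_index(x, spec$origin[2], spec$voxel_pitch[2], spec$grid_shape[2])
  img$values[iz, ix]
}

#' Random scatterer field over a phantom
#'
#' Scatterers are placed uniformly at random over the grid extent; amplitudes
#' are standard Gaussian draws multiplied by the local feature amplitude
#' ratio, so inclusions scatter proportionally more strongly -- the standard
#' construction for fully developed speckle.
#'
#' @param spec a `phantom_spec`.
#' @param n number of scatterers (>= 1); 5e5 gives fully developed speckle at
#'   the default grid.
#' @param seed RNG seed (integer).
#' @return A `scatterer_set`: list with `positions` (n x 2 matrix, columns
#'   x and z in mm), `amplitudes`, `raw_amplitudes` (the unit Gaussian draws)
#'   and `seed`.
#' @export
scatter_field <- function(spec, n = 500000L, seed = 1L) {
  if (!is_scalar_num(n) || n < 1) stop_arg("n must be a positive count")
  n <- as.integer(n)
  ext <- grid_extent(spec)
  img <- rasterize_phantom(spec)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    x <- stats::runif(n, ext$x[1], ext$x[2])
    z <- stats::runif(n, ext$z[1], ext$z[2])
    a <- stats::rnorm(n)
  })
  iz <- pmin(pmax(as.integer(round((z - spec$origin[1]) / spec$voxel_pitch[1])) + 1L, 1L),
             spec$grid_shape[1])
  ix <- pmin(pmax(as.integer(round((x - spec$origin[2]) / spec$voxel_pitch[2])) + 1L, 1L),
             spec$grid_shape[2])
  ratio <- img$values[cbind(iz, ix)] / spec$background
  structure(list(positions = cbind(x = x, z = z),
                 amplitudes = a * ratio, raw_amplitudes = a, seed = seed),
            class = "scatterer_set")
}
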
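# Phantom-plane convention used throughout: coordinates in mm, origin at the
# phantom centre, x to the right, y towards the gantry. Images are row-major
# matrices; pixel (1, 1) is the top-left corner and pixel centres map to
# imager-plane mm through the pixel spacing (see portal_image()).

#' Spatial frequency of a lamella block
#'
#' A line-pair phantom block with equal bar and gap width `w` presents one
#' line pair per `2 w`, i.e. a spatial frequency of `1 / (2 w)` lp/mm.
#'
#' @param width Bar (= gap) width in mm, vectorised, > 0.
#' @return Frequency in lp/mm.
#' @export
#' @examples
#' lamella_frequency(c(4, 1, 0.15))
lamella_frequency <- function(width) {
  if (any(width <= 0)) stop("`width` must be positive", call. = FALSE)
  1 / (2 * width)
}

# Bar widths of the 11 high-contrast lamella sets (mm), largest first.
ptw_lamella_widths <- c(4, 3, 2, 1.5, 1, 0.75, 0.5, 0.35, 0.25, 0.2, 0.15)

# Low-contrast element: hole diameters (mm) and the depth series present for
# each diameter. 27 holes in total: the two largest diameters omit the
# deepest rows.
ptw_hole_depths <- list(
  `15`  = c(0.5, 1.0, 2.0),
  `10`  = c(0.5, 1.0, 2.0, 3.2),
  `7`   = c(0.5, 1.0, 2.0, 3.2, 4.8),
  `4`   = c(0.5, 1.0, 2.0, 3.2, 4.8),
  `2`   = c(0.5, 1.0, 2.0, 3.2, 4.8),
  `1.1` = c(0.5, 1.0, 2.0, 3.2, 4.8)
)

#' Default QC phantom description
#'
#' Builds the geometric specification of the QC phantom used for portal-image
#' quality assessment: 11 high-contrast brass lamella (bar-pattern) sets
#' spanning 0.125-3.33 lp/mm, and an aluminium low-contrast test element with
#' 27 holes of 6 diameters and 5 depths. The diameters, depths and bar widths
#' are the vendor-published values; the layout coordinates (a grid with one
#' column per hole diameter and one row per depth, and a 4 x 3 grid of
#' lamella blocks) are a documented synthetic arrangement, since the
#' commercial phantom's internal drawing is not published. Analyses take
#' their regions of interest from this specification, so any consistent
#' layout is equivalent.
#'
#' The `"extended"` variant adds diagonal-orientation duplicates of the three
#' lowest frequencies (14 lamella sets in total, still 11 distinct
#' frequencies); the duplicates are rendered but not used for MTF extraction.
#'
#' @param variant `"minimal"` (11 lamella sets) or `"extended"` (14).
#' @return A `phantom_spec` object with elements `lamella_blocks` (data
#'   frame: width, frequency, x_start, y_center, n_periods, height,
#'   orientation), `contrast_holes` (data frame: diameter, depth, x, y),
#'   material/thickness fields and layout rectangles (mm).
#' @export
#' @examples
#' ph <- default_ptw_phantom()
#' nrow(ph$contrast_holes)
default_ptw_phantom <- function(variant = c("minimal", "extended")) {
  variant <- match.arg(variant)

  widths <- ptw_lamella_widths
  n_periods <- pmax(4, pmin(20, floor(40 / (2 * widths))))
  col_x <- c(-110, -62, -14, 34)
  row_y <- c(78, 54, 30)
  idx <- seq_along(widths) - 1L
  blocks <- data.frame(
    width = widths,
    frequency = lamella_frequency(widths),
    x_start = col_x[idx %% 4L + 1L],
    y_center = row_y[idx %/% 4L + 1L],
    n_periods = n_periods,
    height = 14,
    orientation = "horizontal",
    stringsAsFactors = FALSE
  )
  if (variant == "extended") {
    # diagonal duplicates of the three lowest frequencies, shortened to fit
    # the free band between the low-contrast element and the bar rows
    dup <- blocks[blocks$width %in% c(4, 3, 2), ]
    dup$x_start <- c(-105, -60, -15)
    dup$y_center <- 7
    dup$n_periods <- c(2L, 2L, 3L)
    dup$height <- 10
    dup$orientation <- "diagonal"
    blocks <- rbind(blocks, dup)
  }

  hole_x <- c(`15` = -100, `10` = -64, `7` = -28, `4` = 8, `2` = 44, `1.1` = 80)
  depth_y <- c(`0.5` = -10, `1` = -34, `2` = -58, `3.2` = -82, `4.8` = -106)
  holes <- do.call(rbind, lapply(names(ptw_hole_depths), function(d) {
    depths <- ptw_hole_depths[[d]]
    data.frame(diameter = as.numeric(d), depth = depths,
               x = unname(hole_x[d]),
               y = unname(depth_y[as.character(depths)]))
  }))
  rownames(holes) <- NULL

  structure(
    list(
      lamella_blocks = blocks,
      contrast_holes = holes,
      base_material = "acrylic", base_thickness = 6,
      element_material = "aluminum", element_thickness = 2,
      lamella_material = "brass", lamella_thickness = 2,
      # rectangles as c(x0, x1, y0, y1), phantom-plane mm
      element_region = c(-120, 100, -122, 2),
      footprint = c(-122, 102, -124, 94),
      variant = variant
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d lamella sets (%d frequencies, %.3g-%.3g lp/mm), %d holes (%d diameters x %d depths)\n",
    nrow(x$lamella_blocks), length(unique(x$lamella_blocks$frequency)),
    min(x$lamella_blocks$frequency), max(x$lamella_blocks$frequency),
    nrow(x$contrast_holes), length(unique(x$contrast_holes$diameter)),
    length(unique(x$contrast_holes$depth))
  ))
  invisible(x)
}

#' Imaging geometry
#'
#' @param ssd Source-to-surface (phantom) distance in cm; default 95.2.
#' @param sid Source-to-imager distance in cm; default 110.
#' @param field_size Field size at the phantom plane, cm (width, height);
#'   default 26 x 26.
#' @return An `imaging_geometry` object.
#' @export
imaging_geometry <- function(ssd = 95.2, sid = 110, field_size = c(26, 26)) {
  if (!(sid >= ssd && ssd > 0)) {
    stop("require sid >= ssd > 0", call. = FALSE)
  }
  if (length(field_size) == 1) field_size <- rep(field_size, 2)
  if (any(field_size <= 0)) stop("`field_size` must be positive", call. = FALSE)
  structure(list(ssd = ssd, sid = sid, field_size = field_size),
            class = "imaging_geometry")
}

#' Projection magnification
#'
#' Ratio of source-imager to source-surface distance; maps phantom-plane mm
#' to imager-plane mm. Phantom-plane spatial frequency `f` appears at
#' `f / magnification` on the imager.
#'
#' @param geom An [imaging_geometry()].
#' @return Magnification factor (>= 1 for sid >= ssd).
#' @export
#' @examples
#' magnification(imaging_geometry(ssd = 95.2, sid = 110))
magnification <- function(geom) {
  stopifnot(inherits(geom, "imaging_geometry"))
  geom$sid / geom$ssd
}

#' Serialize / load a phantom specification
#'
#' YAML with `lamellae: [{width_mm, x_start_mm, y_center_mm, n_periods,
#' height_mm, orientation}, ...]` and `holes: [{diameter_mm, depth_mm, x_mm,
#' y_mm}, ...]` plus the material/region fields.
#'
#' @param phantom A `phantom_spec`.
#' @param path File path.
#' @return `write_phantom_spec` returns `path` invisibly; `read_phantom_spec`
#'   the `phantom_spec`.
#' @export
write_phantom_spec <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_spec"))
  b <- phantom$lamella_blocks
  h <- phantom$contrast_holes
  obj <- list(
    lamellae = lapply(seq_len(nrow(b)), function(i) list(
      width_mm = b$width[i], x_start_mm = b$x_start[i],
      y_center_mm = b$y_center[i], n_periods = b$n_periods[i],
      height_mm = b$height[i], orientation = b$orientation[i]
    )),
    holes = lapply(seq_len(nrow(h)), function(i) list(
      diameter_mm = h$diameter[i], depth_mm = h$depth[i],
      x_mm = h$x[i], y_mm = h$y[i]
    )),
    base_material = phantom$base_material,
    base_thickness_mm = phantom$base_thickness,
    element_material = phantom$element_material,
    element_thickness_mm = phantom$element_thickness,
    lamella_material = phantom$lamella_material,
    lamella_thickness_mm = phantom$lamella_thickness,
    element_region_mm = as.list(phantom$element_region),
    footprint_mm = as.list(phantom$footprint),
    variant = phantom$variant
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  for (key in c("lamellae", "holes")) {
    if (is.null(obj[[key]])) {
      stop("phantom spec is missing `", key, "`", call. = FALSE)
    }
  }
  blocks <- do.call(rbind, lapply(obj$lamellae, function(l) data.frame(
    width = l$width_mm, frequency = lamella_frequency(l$width_mm),
    x_start = l$x_start_mm, y_center = l$y_center_mm,
    n_periods = l$n_periods, height = l$height_mm,
    orientation = l$orientation, stringsAsFactors = FALSE
  )))
  holes <- do.call(rbind, lapply(obj$holes, function(h) data.frame(
    diameter = h$diameter_mm, depth = h$depth_mm, x = h$x_mm, y = h$y_mm
  )))
  structure(
    list(
      lamella_blocks = blocks, contrast_holes = holes,
      base_material = obj$base_material,
      base_thickness = obj$base_thickness_mm,
      element_material = obj$element_material,
      element_thickness = obj$element_thickness_mm,
      lamella_material = obj$lamella_material,
      lamella_thickness = obj$lamella_thickness_mm,
      element_region = unlist(obj$element_region_mm),
      footprint = unlist(obj$footprint_mm),
      variant = obj$variant %||% "minimal"
    ),
    class = "phantom_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
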
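readRaster <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format \"%s\" (supported: png, jpeg)", ext)))
  if (length(dim(img)) == 3 && dim(img)[3] == 4)
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Load the two views, separately or from a composite
#'
#' With two paths the images are loaded unchanged. With a single composite
#' the two views must have been merged along a shared dimension: a composite
#' at least twice as wide as tall is split into left/right halves, one at
#' least twice as tall as wide into top/bottom halves; anything else is
#' rejected with a merge-rule error. By default the top view is the left
#' (or upper) pane.
#'
#' @param pathA path to the top-view image, or to the composite.
#' @param pathB path to the side-view image, or NULL for a composite.
#' @param topFirst composite pane order: top view is the left/upper pane
#'   (default TRUE).
#' @return list of two RGB rasters, `top` and `side` (H x W x 3 in \[0,1\]).
#' @export
loadImages <- function(pathA, pathB = NULL, topFirst = TRUE) {
  if (!is.null(pathB)) {
    return(list(top = readRaster(pathA), side = readRaster(pathB)))
  }
  img <- readRaster(pathA)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (w >= 2 * h && w %% 2 == 0) {
    a <- img[, 1:(w / 2), , drop = FALSE]
    b <- img[, (w / 2 + 1):w, , drop = FALSE]
  } else if (h >= 2 * w && h %% 2 == 0) {
    a <- img[1:(h / 2), , , drop = FALSE]
    b <- img[(h / 2 + 1):h, , , drop = FALSE]
  } else {
    stop(sprintf(paste0("cannot split composite %dx%d: neither dimension is ",
                        "twice the other; load the views separately"), w, h))
  }
  if (topFirst) list(top = a, side = b) else list(top = b, side = a)
}

viewToList <- function(v) {
  list(label = v@label, rotation_deg = v@rotationDeg,
       translation = v@translation)
}

viewFromList <- function(l) {
  viewTransform(unlist(l$rotation_deg), unlist(l$translation),
                l$label %||% "view")
}

#' Save / load a session as versioned JSON
#'
#' All numeric state (eye model, views, marks, results, pixel scale) is
#' written at full precision; images are referenced by path and MD5 checksum
#' rather than embedded. On load the schema version is checked, every
#' invariant re-validated (an out-of-range rim angle, for example, is
#' rejected naming the field), and a checksum mismatch raises a warning.
#'
#' @param session an [EyeSession-class].
#' @param path file path for the JSON session.
#' @return `saveSession` returns `path` invisibly; `loadSession` returns the
#'   [EyeSession-class].
#' @export
saveSession <- function(session, path) {
  stopifnot(is(session, "EyeSession"))
  obj <- list(
    schema_version = session@schemaVersion,
    pixel_scale = session@pixelScale,
    eye = list(semi_axes = session@eye@semiAxes,
               rim_opening_deg = session@eye@rimOpeningDeg,
               handedness = session@eye@handedness),
    views = lapply(session@views, viewToList),
    images = session@images,
    marks = lapply(session@marks, function(m)
      list(label = m@label, pixel = m@pixel)),
    results = session@results,
    provenance = session@provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname saveSession
#' @export
loadSession <- function(path) {
  if (!file.exists(path)) stop(sprintf("session file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || !identical(obj$schema_version, "1.0"))
    stop(sprintf("unsupported session schema version \"%s\" (expected 1.0)",
                 obj$schema_version %||% "<missing>"))
  rim <- obj$eye$rim_opening_deg
  if (is.null(rim) || rim <= 0 || rim >= 90)
    stop("invalid session field eye$rim_opening_deg: must lie in (0, 90)")
  eye <- eyeModel(unlist(obj$eye$semi_axes), rim, obj$eye$handedness)
  views <- lapply(seq_len(nrow_or_len(obj$views)), function(i)
    viewFromList(pick_row(obj$views, i)))
  names(views) <- vapply(views, viewLabel, character(1))
  marks <- list()
  if (!is.null(obj$marks) && nrow_or_len(obj$marks) > 0)
    marks <- lapply(seq_len(nrow_or_len(obj$marks)), function(i) {
      m <- pick_row(obj$marks, i)
      viewMark(unlist(m$pixel), m$label %||% "view")
    })
  images <- if (is.null(obj$images)) list() else obj$images
  if (length(images)) {
    for (nm in names(images)) {
      info <- images[[nm]]
      if (!is.null(info$path) && !is.null(info$checksum) &&
          file.exists(info$path)) {
        sum <- unname(tools::md5sum(info$path))
        if (!identical(sum, info$checksum))
          warning(sprintf("checksum mismatch for %s image \"%s\"", nm, info$path))
      }
    }
  }
  new("EyeSession", schemaVersion = obj$schema_version,
      images = images, pixelScale = obj$pixel_scale %||% 1,
      eye = eye, views = views, marks = marks,
      results = if (is.null(obj$results)) list() else obj$results,
      provenance = if (is.null(obj$provenance)) list() else obj$provenance)
}

# jsonlite may simplify a list of records to a data.frame; handle both
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
pick_row <- function(x, i) {
  if (is.data.frame(x)) lapply(x, function(col)
    if (is.list(col)) col[[i]] else col[i])
  else x[[i]]
}

#' Image reference entry for a session
#'
#' @param path image file path.
#' @return list with path, checksum and pixel dimensions.
#' @export
imageRef <- function(path) {
  img <- readRaster(path)
  list(path = path, checksum = unname(tools::md5sum(path)),
       width = dim(img)[2], height = dim(img)[1])
}

#' Export a localization result in flat polar form
#'
#' Writes a one-row CSV (`colatitude_deg`, `azimuth_deg`, `nt_fraction`,
#' `dv_fraction`, `area_fraction`) and, optionally, a polar-plot figure: the
#' retina viewed from its deepest point, the rim drawn as a circle at the
#' rim colatitude (127 degrees for a 53-degree opening), and the injection
#' as a dot scaled so its plotted radius reflects the estimated area.
#'
#' @param result a [LocalizationResult-class].
#' @param eye the [EyeModel-class] used.
#' @param csvPath output CSV path.
#' @param figPath optional PNG figure path.
#' @return `csvPath`, invisibly.
#' @export
exportFlat <- function(result, eye, csvPath, figPath = NULL) {
  df <- data.frame(colatitude_deg = result@polar[1],
                   azimuth_deg = result@polar[2],
                   nt_fraction = result@ntFraction,
                   dv_fraction = result@dvFraction,
                   area_fraction = result@areaFraction)
  utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(figPath)) {
    phi0 <- rimColatitude(eye)
    grDevices::png(figPath, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(2, 2, 3, 2))
    graphics::plot(NA, xlim = c(-140, 140), ylim = c(-140, 140), asp = 1,
                   axes = FALSE, xlab = "", ylab = "",
                   main = "Injection location (polar view from the deepest point)")
    tt <- seq(0, 2 * pi, length.out = 361)
    graphics::lines(phi0 * cos(tt), phi0 * sin(tt), col = "goldenrod", lwd = 2)
    for (ring in c(30, 60, 90))
      graphics::lines(ring * cos(tt), ring * sin(tt), col = "grey80")
    az <- deg2rad(result@polar[2])
    r <- result@polar[1]
    dotR <- 3
    if (!is.na(result@areaFraction) && result@areaFraction > 0) {
      zr <- -cos(deg2rad(phi0))
      half <- rad2deg(acos(max(-1, 1 - result@areaFraction * (1 - (-zr)))))
      dotR <- max(dotR, half)
    }
    graphics::symbols(r * cos(az), r * sin(az), circles = dotR,
                      inches = FALSE, add = TRUE, bg = "#8c1428", fg = NA)
    graphics::text(phi0 + 8, 0, sprintf("rim %g°", phi0), cex = 0.9)
  }
  invisible(csvPath)
}
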
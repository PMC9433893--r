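#' Write a frameset to a self-describing HDF5 container
#'
#' One file holds the acquisition geometry, the optional ground-truth label,
#' and every frame's RF matrix with its wavelength/trial/frame/energy
#' metadata. [read_frameset()] inverts the operation exactly (full-precision
#' arrays, bit-exact metadata).
#'
#' @param fs A [frameset()].
#' @param path Output file path.
#' @param overwrite Overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_frameset <- function(fs, path, overwrite = FALSE) {
  if (!inherits(fs, "pa_frameset"))
    stop("fs must be a pa_frameset", call. = FALSE)
  if (file.exists(path) && !overwrite)
    stop(sprintf("'%s' exists; use overwrite = TRUE to replace it", path),
         call. = FALSE)
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop(sprintf("cannot create '%s'", path), call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  g <- fs$geometry
  rhdf5::h5createGroup(path, "geometry")
  for (nm in c("n_elements", "pitch", "fs", "c", "fc", "axial_spacing",
               "lateral_spacing"))
    rhdf5::h5write(g[[nm]], path, paste0("geometry/", nm))
  if (!is.null(fs$ground_truth))
    rhdf5::h5write(fs$ground_truth, path, "ground_truth")

  rhdf5::h5createGroup(path, "frames")
  for (i in seq_along(fs$frames)) {
    f <- fs$frames[[i]]
    grp <- sprintf("frames/f%04d", i)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(f$rf, path, paste0(grp, "/rf"))
    rhdf5::h5write(f$wavelength, path, paste0(grp, "/wavelength"))
    rhdf5::h5write(f$trial, path, paste0(grp, "/trial"))
    rhdf5::h5write(f$frame, path, paste0(grp, "/frame"))
    rhdf5::h5write(f$energy, path, paste0(grp, "/energy"))
  }
  invisible(path)
}

#' Read a frameset from an HDF5 container
#'
#' @param path A file written by [write_frameset()].
#' @return A [frameset()].
#' @export
read_frameset <- function(path) {
  if (!file.exists(path)) stop(sprintf("'%s' not found", path), call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  paths <- paste0(sub("^/$", "", contents$group), "/", contents$name)

  need_geom <- paste0("/geometry/",
                      c("n_elements", "pitch", "fs", "c", "fc",
                        "axial_spacing", "lateral_spacing"))
  missing_geom <- setdiff(need_geom, paths)
  if (!"/geometry" %in% paths || length(missing_geom) > 0L) {
    miss <- if (!"/geometry" %in% paths) "geometry"
            else sub("^/geometry/", "geometry/", missing_geom[1])
    stop(sprintf("format error: missing field '%s' in '%s'", miss, path),
         call. = FALSE)
  }
  rd <- function(p) {
    v <- rhdf5::h5read(path, p)
    if (is.array(v) && length(dim(v)) <= 1L) v <- as.vector(v)
    v
  }
  geom <- acquisition_geometry(
    n_elements = rd("geometry/n_elements"), pitch = rd("geometry/pitch"),
    fs = rd("geometry/fs"), c = rd("geometry/c"), fc = rd("geometry/fc"),
    axial_spacing = rd("geometry/axial_spacing"),
    lateral_spacing = rd("geometry/lateral_spacing"))
  gt <- if ("/ground_truth" %in% paths) rd("ground_truth") else NULL

  fgroups <- sort(unique(contents$group[grepl("^/frames/f", contents$group)]))
  if (length(fgroups) == 0L) stop("no frames", call. = FALSE)
  frames <- lapply(fgroups, function(grp) {
    for (fld in c("rf", "wavelength", "trial", "frame", "energy"))
      if (!paste0(grp, "/", fld) %in% paths)
        stop(sprintf("format error: missing field '%s' in frame '%s'",
                     fld, grp), call. = FALSE)
    channel_frame(rf = rhdf5::h5read(path, paste0(grp, "/rf")),
                  wavelength = rd(paste0(grp, "/wavelength")),
                  trial = rd(paste0(grp, "/trial")),
                  frame = rd(paste0(grp, "/frame")),
                  energy = rd(paste0(grp, "/energy")))
  })
  frameset(frames, geom, ground_truth = gt)
}
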
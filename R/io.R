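#' Read / write volumes
#'
#' Volumes round-trip losslessly (values, dimensions, voxel size) through
#' MetaImage (\code{.mhd} header + \code{.raw} block, or single-file
#' \code{.mha}) and NIfTI (\code{.nii}, \code{.nii.gz}). The format is
#' picked from the file extension.
#'
#' @param path File path ending in \code{.mhd}, \code{.mha}, \code{.nii} or
#'   \code{.nii.gz}.
#' @return \code{read_volume}: a \code{ct_volume}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mhd", "mha")) return(read_mhd(path))
  if (ext == "nii" || grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    v <- as.array(img)
    v <- array(as.numeric(v), dim(v))   # strip image attributes
    if (length(dim(v)) == 2) dim(v) <- c(dim(v), 1L)
    vs <- RNifti::pixdim(img)[1]
    return(ct_volume(volume_grid(dim(v)[1], dim(v)[2], dim(v)[3], vs), v))
  }
  stop(sprintf("unsupported volume format: .%s", ext), call. = FALSE)
}

#' @rdname read_volume
#' @param vol A \code{ct_volume}.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mhd", "mha")) return(write_mhd(vol, path))
  if (ext == "nii" || grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) {
    vs <- vol$grid$voxel_size
    img <- RNifti::asNifti(vol$values,
                           reference = list(pixdim = c(-1, vs, vs, vs, 1, 1, 1, 1)),
                           datatype = "double")
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  stop(sprintf("unsupported volume format: .%s", ext), call. = FALSE)
}

# -- MetaImage (.mhd/.mha), double-precision little-endian raw block --------

write_mhd <- function(vol, path) {
  ext <- tolower(tools::file_ext(path))
  local_data <- ext == "mha"
  raw_name <- if (local_data) "LOCAL" else paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  d <- dim(vol$values)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", vol$grid$voxel_size,
            vol$grid$voxel_size, vol$grid$voxel_size),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", raw_name))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.vector(vol$values), con, size = 8, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), raw_name), "wb")
    writeBin(as.vector(vol$values), rcon, size = 8, endian = "little")
    close(rcon)
  }
  invisible(path)
}

read_mhd <- function(path) {
  lines <- character()
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  repeat {
    ln <- readLines(con, n = 1, warn = FALSE)
    if (length(ln) == 0) break
    lines <- c(lines, ln)
    if (grepl("^ElementDataFile", ln)) break
  }
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2
  if (any(bad) || length(lines) == 0)
    stop(sprintf("corrupted MetaImage header in %s", path), call. = FALSE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop(sprintf("MetaImage header missing %s", k), call. = FALSE)
    vals[i]
  }
  if (get("ElementType") != "MET_DOUBLE")
    stop("only MET_DOUBLE MetaImage volumes are supported", call. = FALSE)
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  n <- prod(d)
  datafile <- get("ElementDataFile")
  if (identical(datafile, "LOCAL")) {
    v <- readBin(con, "double", n = n, size = 8, endian = "little")
  } else {
    rpath <- file.path(dirname(path), datafile)
    if (!file.exists(rpath))
      stop(sprintf("MetaImage data file not found: %s", rpath), call. = FALSE)
    v <- readBin(rpath, "double", n = n, size = 8, endian = "little")
  }
  if (length(v) != n)
    stop(sprintf("MetaImage data block truncated in %s", path), call. = FALSE)
  ct_volume(volume_grid(d[1], d[2], d[3], sp[1]), array(v, d))
}

#' Read / write projection stacks
#'
#' Projections are stored as a 32-bit float multi-page TIFF (one page per
#' angle, u along rows, v along columns) next to a YAML geometry sidecar
#' \code{<stem>.geom.yaml} holding the full \code{scan_geometry} including
#' the angle list. Both files are required to reload a stack.
#'
#' Pages are normalized to [0, 1] for storage (TIFF float samples outside
#' that range are not portable); the affine scale and offset are recorded in
#' the sidecar and undone on read, so the round-trip preserves values to
#' single precision.
#'
#' @param path TIFF file path (\code{.tif}/\code{.tiff}).
#' @return \code{read_projections}: a \code{projection_stack}.
#' @export
read_projections <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  sidecar <- geom_sidecar_path(path)
  if (!file.exists(sidecar))
    stop(sprintf("missing geometry sidecar: expected %s", sidecar),
         call. = FALSE)
  side <- yaml::read_yaml(sidecar)
  geom <- geometry_from_list(side$geometry)
  offset <- if (is.null(side$value_offset)) 0 else side$value_offset
  scale <- if (is.null(side$value_scale)) 1 else side$value_scale
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  na <- length(geom$angles)
  if (length(pages) != na)
    stop(sprintf("TIFF has %d pages but geometry lists %d angles",
                 length(pages), na), call. = FALSE)
  arr <- array(0, c(geom$det_pixels_u, geom$det_pixels_v, na))
  for (i in seq_len(na)) {
    pg <- pages[[i]]
    if (is.matrix(pg)) arr[, , i] <- pg else arr[, , i] <- matrix(pg, geom$det_pixels_u)
  }
  projection_stack(geom, arr * scale + offset)
}

#' @rdname read_projections
#' @param stack A \code{projection_stack}.
#' @export
write_projections <- function(stack, path) {
  stopifnot(inherits(stack, "projection_stack"))
  na <- length(stack$geometry$angles)
  lo <- min(stack$values)
  hi <- max(stack$values)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(na), function(i) {
    m <- stack$values[, , i]
    if (!is.matrix(m)) m <- matrix(m, dim(stack$values)[1])
    (m - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(geometry = geometry_to_list(stack$geometry),
                        value_offset = lo, value_scale = scale),
                   geom_sidecar_path(path))
  invisible(path)
}

geom_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".geom.yaml")
}
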
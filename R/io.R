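#' Read / write label volumes
#'
#' Scenes round-trip through the two common medical label-volume formats:
#' NIfTI (`.nii` / `.nii.gz`, via RNifti) and MetaImage (`.mha`, single
#' file, written by a minimal reader/writer of the uncompressed format).
#' Labels, spacing and origin are preserved exactly; volumes must be
#' integer-labeled and codes must belong to the role map.
#'
#' @param path File path ending in `.nii`, `.nii.gz` or `.mha`.
#' @param scene A [label_scene()].
#' @param roles Role map the labels must belong to (default
#'   [scene_roles()]).
#' @return `read_label_volume()` returns a [label_scene()];
#'   `write_label_volume()` returns `path` invisibly.
#' @export
write_label_volume <- function(scene, path) {
  stopifnot(inherits(scene, "label_scene"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    mat <- diag(c(scene$spacing, 1))
    mat[1:3, 4] <- scene$origin
    lab <- scene$labels
    attr(lab, "pixdim") <- scene$spacing
    img <- RNifti::asNifti(lab, datatype = "int32")
    RNifti::qform(img) <- structure(mat, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", path)) {
    write_mha(scene$labels, scene$spacing, scene$origin, path)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path, roles = scene_roles()) {
  if (is.null(roles)) stop("a role map is required to interpret label codes")
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    lab <- array(as.vector(img), dim = dim(img))
    if (any(lab != round(lab))) stop("volume is not integer-labeled: ", path)
    spacing <- attr(img, "pixdim")[1:3]
    xf <- RNifti::xform(img)
    origin <- xf[1:3, 4]
    # NIfTI xforms are RAS; our writer stores a positive diagonal, but a
    # reader may hand back flipped axes -- undo pure sign flips
    for (a in 1:3) if (xf[a, a] < 0) {
      lab <- flip_axis(lab, a)
      origin[a] <- origin[a] + xf[a, a] * (dim(lab)[a] - 1)
    }
  } else if (grepl("\\.mha$", path)) {
    m <- read_mha(path)
    lab <- m$data; spacing <- m$spacing; origin <- m$origin
  } else stop("unsupported volume format: ", path)
  storage.mode(lab) <- "integer"
  bad <- setdiff(unique(as.vector(lab)), unname(roles))
  if (length(bad))
    stop("unknown label code(s) in ", path, ": ", paste(bad, collapse = ", "))
  label_scene(lab, spacing = spacing, origin = origin,
              meta = list(kind = "file", source = path))
}

flip_axis <- function(a, axis) {
  idx <- lapply(dim(a), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(a), idx))
}

# -- minimal MetaImage (.mha, LOCAL uncompressed) support ------------------

write_mha <- function(data, spacing, origin, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(origin, scientific = FALSE), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(format(spacing, scientific = FALSE), collapse = " ")),
    paste("DimSize =", paste(dim(data), collapse = " ")),
    "ElementType = MET_INT",
    "ElementDataFile = LOCAL"
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.integer(data), con, size = 4L, endian = "little")
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("only single-file (LOCAL) MetaImage volumes are supported")
  if (!identical(hdr$ElementType, "MET_INT"))
    stop("unsupported MetaImage element type: ", hdr$ElementType)
  if (identical(hdr$CompressedData, "True"))
    stop("compressed MetaImage volumes are not supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  n <- prod(dims)
  vals <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  list(data = array(vals, dim = dims),
       spacing = as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]),
       origin = as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]))
}

#' Export a field envelope as a legacy VTK structured-points file
#'
#' Writes `E_max` (V/cm), `sigma` (S/m) and the label codes as point data
#' on the voxel grid, readable by ParaView and any standard VTK reader.
#'
#' @param envelope A [solve_sequence()] `field_envelope`.
#' @param scene The matching [label_scene()].
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
export_field_vtk <- function(envelope, scene, path) {
  if (!identical(dim(scene$labels), envelope$dims))
    stop("envelope and scene grids differ")
  d <- envelope$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "ectfield field envelope",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", d[1], d[2], d[3]),
    paste("ORIGIN", paste(scene$origin, collapse = " ")),
    paste("SPACING", paste(scene$spacing, collapse = " ")),
    paste("POINT_DATA", prod(d)),
    "SCALARS E_max float 1",
    "LOOKUP_TABLE default"
  ), con)
  writeLines(format(as.vector(envelope$E_max), digits = 6, trim = TRUE), con)
  writeLines(c("SCALARS sigma float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(envelope$sigma), digits = 6, trim = TRUE), con)
  writeLines(c("SCALARS labels int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.vector(scene$labels)), con)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' A study configuration collects tissue overrides, discretization and
#' solver settings, optimizer bounds, and a seed; a short content hash is
#' attached so every output table can be stamped with the configuration it
#' came from.
#'
#' @param path YAML file path.
#' @return List of class `study_config` with a `hash` attribute.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "study_config", hash = config_hash(cfg))
}

#' Content hash of a configuration object
#'
#' 32-bit polynomial rolling hash over the canonical serialization; used
#' to stamp outputs so tables can be traced back to the configuration that
#' produced them (not cryptographic).
#'
#' @param cfg Any R object.
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(cfg) {
  raw <- serialize(cfg, NULL, version = 2)
  b <- as.integer(raw)
  # split the 32-bit state into two 16-bit halves to stay in exact-double
  # integer range while multiplying by the 16-bit prime 40503
  hi <- 0; lo <- 0
  for (x in b) {
    lo2 <- lo * 40503 + x
    hi2 <- hi * 40503 + lo2 %/% 65536
    lo <- lo2 %% 65536
    hi <- hi2 %% 65536
  }
  sprintf("%04x%04x", hi, lo)
}
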
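#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers around RNifti preserving this package's grid convention
#' (axis-aligned direction, world = origin + index * spacing). Writing then
#' reading is the identity on data, spacing and origin up to float round-off.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_nifti` returns a [volume()]; `write_nifti` returns the path,
#'   invisibly.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(img)), "D",
         call. = FALSE)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)), 1)))
    stop("oblique NIfTI orientations are not supported", call. = FALSE)
  spacing <- abs(diag(rot))
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  dat <- array(as.numeric(img), dim = dim(img))
  # reorient flipped axes so stored spacing is positive
  for (ax in 1:3) {
    if (diag(rot)[ax] < 0) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[ax]] <- dim(dat)[ax]:1
      dat <- do.call(`[`, c(list(dat), idx, drop = FALSE))
      origin[ax] <- origin[ax] - spacing[ax] * (dim(dat)[ax] - 1)
    }
  }
  volume(dat, spacing = spacing, origin = origin)
}

#' @rdname read_nifti
#' @param v a [volume()] or [label_volume()] (labels are written as integers).
#' @export
write_nifti <- function(v, path) {
  dat <- array(as.vector(v), dim = dim(v))
  img <- RNifti::asNifti(dat)
  sp <- vol_spacing(v); o <- vol_origin(v)
  RNifti::`pixdim<-`(img, sp) -> img
  mat <- diag(4)
  diag(mat)[1:3] <- sp
  mat[1:3, 4] <- o
  RNifti::`sform<-`(img, structure(mat, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(mat, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal DICOM series reader: uncompressed single-frame scalar slices,
# explicit or implicit VR little-endian. No R DICOM package exists in this
# stack, so the byte-level parse is done here; only the tags the pipeline
# needs are interpreted.
# ---------------------------------------------------------------------------

dcm_uint <- function(raw) sum(as.numeric(raw) * 256^(seq_along(raw) - 1))

dcm_tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

# parse one DICOM file into a list of tag -> raw value
dcm_parse <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  pos <- 133L
  n <- length(bytes)
  tags <- list()
  explicit <- TRUE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  read_elem <- function(pos, in_meta) {
    if (pos + 7L > n) return(NULL)
    group <- dcm_uint(bytes[pos:(pos + 1)])
    elem <- dcm_uint(bytes[(pos + 2):(pos + 3)])
    pos <- pos + 4L
    use_explicit <- if (in_meta) TRUE else explicit
    if (use_explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1)])
      if (vr %in% long_vrs) {
        len <- dcm_uint(bytes[(pos + 4):(pos + 7)])
        pos <- pos + 8L
      } else {
        len <- dcm_uint(bytes[(pos + 2):(pos + 3)])
        pos <- pos + 4L
      }
    } else {
      vr <- "UN"
      len <- dcm_uint(bytes[pos:(pos + 3)])
      pos <- pos + 4L
    }
    list(group = group, elem = elem, vr = vr, len = len, pos = pos)
  }
  meta_end <- Inf
  while (pos <= n) {
    in_meta <- is.finite(meta_end) || pos < meta_end
    e <- read_elem(pos, in_meta = pos < meta_end || dcm_uint(bytes[pos:(pos + 1)]) == 2)
    if (is.null(e)) break
    if (e$group == 2 && e$elem == 0 && !is.finite(meta_end)) {
      glen <- dcm_uint(bytes[e$pos:(e$pos + e$len - 1)])
      meta_end <- e$pos + e$len + glen
    }
    if (e$len == 4294967295) { # undefined length (sequences): not supported
      stop("undefined-length DICOM sequences are not supported", call. = FALSE)
    }
    val <- if (e$len > 0) bytes[e$pos:(e$pos + e$len - 1)] else raw(0)
    key <- dcm_tag_key(e$group, e$elem)
    if (e$group == 2 && e$elem == 16) {
      ts <- sub("\\s+$", "", rawToChar(val))
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (!ts %in% c("1.2.840.10008.1.2.1"))
        stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
    }
    if (e$vr != "SQ") tags[[key]] <- list(vr = e$vr, value = val)
    pos <- e$pos + e$len
  }
  tags
}

dcm_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NA_character_)
  sub("\\s+$", "", rawToChar(t$value))
}

dcm_num <- function(tags, key) {
  s <- dcm_str(tags, key)
  if (is.na(s) || !nzchar(s)) return(NA_real_)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NA_integer_)
  as.integer(dcm_uint(t$value[1:2]))
}

#' Read a DICOM series as a volume
#'
#' Reads one single-series stack of uncompressed scalar DICOM slices
#' (explicit or implicit VR little-endian), sorts slices by their position
#' along the slice normal, and assembles a [volume()] with spacing and origin
#' taken from the metadata. Rescale slope/intercept are applied.
#'
#' @param directory directory containing the `.dcm` files of one series.
#' @return A [volume()].
#' @export
read_dicom_series <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory,
                                   call. = FALSE)
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0)
    stop("DICOM format error: directory contains no files", call. = FALSE)
  parsed <- lapply(files, dcm_parse)
  uids <- vapply(parsed, dcm_str, "", key = "0020,000E")
  if (length(unique(uids[!is.na(uids)])) > 1)
    stop("DICOM format error: directory mixes multiple series", call. = FALSE)
  spp <- vapply(parsed, dcm_us, 1L, key = "0028,0002")
  if (any(!is.na(spp) & spp != 1L))
    stop("DICOM format error: non-scalar pixel data", call. = FALSE)
  slices <- lapply(parsed, function(tags) {
    rows <- dcm_us(tags, "0028,0010"); cols <- dcm_us(tags, "0028,0011")
    bits <- dcm_us(tags, "0028,0100")
    if (is.na(rows) || is.na(cols) || is.null(tags[["7FE0,0010"]]))
      stop("DICOM format error: missing image data tags", call. = FALSE)
    if (!bits %in% c(8L, 16L))
      stop("DICOM format error: unsupported bits allocated: ", bits,
           call. = FALSE)
    signed <- identical(dcm_us(tags, "0028,0103"), 1L)
    pix <- tags[["7FE0,0010"]]$value
    vals <- readBin(pix, what = "integer", n = rows * cols,
                    size = bits / 8L, signed = if (bits == 8L) FALSE else signed,
                    endian = "little")
    if (bits == 16L && !signed) vals <- ifelse(vals < 0, vals + 65536, vals)
    slope <- dcm_num(tags, "0028,1053"); icpt <- dcm_num(tags, "0028,1052")
    if (!is.na(slope[1])) vals <- vals * slope[1]
    if (!is.na(icpt[1])) vals <- vals + icpt[1]
    ipp <- dcm_num(tags, "0020,0032")
    inst <- dcm_num(tags, "0020,0013")
    pxsp <- dcm_num(tags, "0028,0030") # (row, col) spacing
    thick <- dcm_num(tags, "0018,0050")
    list(mat = array(vals, dim = c(cols, rows)), ipp = ipp, inst = inst[1],
         pxsp = pxsp, thick = thick[1])
  })
  dims <- vapply(slices, function(s) dim(s$mat), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("DICOM format error: inconsistent slice dimensions", call. = FALSE)
  pos3 <- vapply(slices, function(s)
    if (length(s$ipp) == 3) s$ipp[3] else NA_real_, 0)
  ord <- if (all(is.finite(pos3))) order(pos3)
         else order(vapply(slices, function(s) s$inst %||% NA_real_, 0))
  slices <- slices[ord]
  nz <- length(slices)
  dat <- array(0, dim = c(dims[1, 1], dims[2, 1], nz))
  for (k in seq_len(nz)) dat[, , k] <- slices[[k]]$mat
  pxsp <- slices[[1]]$pxsp
  if (length(pxsp) != 2 || anyNA(pxsp)) pxsp <- c(1, 1)
  dz <- if (nz > 1 && all(is.finite(pos3)))
    abs(pos3[ord][2] - pos3[ord][1]) else slices[[1]]$thick
  if (is.na(dz) || dz <= 0) dz <- 1
  origin <- slices[[1]]$ipp
  if (length(origin) != 3 || anyNA(origin)) origin <- c(0, 0, 0)
  volume(dat, spacing = c(pxsp[2], pxsp[1], dz), origin = origin)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

# ---------------------------------------------------------------------------
# Mesh writing: ASCII STL and Wavefront OBJ
# ---------------------------------------------------------------------------

#' Write a surface mesh to STL or OBJ
#'
#' @param m a [surface_mesh()].
#' @param path output file.
#' @param format `"STL"` (ASCII) or `"OBJ"`. Defaults to the file extension.
#' @return The path, invisibly.
#' @export
write_mesh <- function(m, path, format = c("auto", "STL", "OBJ")) {
  format <- match.arg(toupper(format[1]), c("AUTO", "STL", "OBJ"))
  if (format == "AUTO")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "OBJ" else "STL"
  if (!inherits(m, "surface_mesh")) stop("not a surface_mesh", call. = FALSE)
  if (nrow(m$vertices) == 0 || nrow(m$faces) == 0)
    stop("refusing to write an empty mesh", call. = FALSE)
  if (max(m$faces) > nrow(m$vertices) || min(m$faces) < 1)
    stop("face index out of range", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  V <- m$vertices; F <- m$faces
  if (format == "OBJ") {
    writeLines(c("# mracad surface mesh",
                 sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
                 sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])), con)
  } else {
    a <- V[F[, 1], , drop = FALSE]; b <- V[F[, 2], , drop = FALSE]
    cc <- V[F[, 3], , drop = FALSE]
    u <- b - a; w <- cc - a
    nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    writeLines("solid mracad", con)
    block <- sprintf(paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
                            "  vertex %.9g %.9g %.9g\n",
                            "  vertex %.9g %.9g %.9g\n",
                            "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
                     nrm[, 1], nrm[, 2], nrm[, 3],
                     a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
                     cc[, 1], cc[, 2], cc[, 3])
    writeLines(block, con)
    writeLines("endsolid mracad", con)
  }
  invisible(path)
}

#' Read a surface mesh written by [write_mesh()]
#'
#' OBJ meshes round-trip exactly; ASCII STL stores one vertex triple per
#' facet, so vertices are re-merged by exact coordinate match on read.
#'
#' @param path `.obj` or `.stl` file.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^v ", lines))) { # OBJ
    vl <- lines[grepl("^v ", lines)]
    fl <- lines[grepl("^f ", lines)]
    V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
      as.numeric(p[2:4])))
    F <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
      as.integer(sub("/.*", "", p[2:4]))))
    return(surface_mesh(V, F))
  }
  vl <- grep("^\\s*vertex ", lines, value = TRUE)
  if (length(vl) == 0) stop("unrecognized mesh file: ", path, call. = FALSE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(coords, 1, function(r) paste(sprintf("%.9g", r), collapse = ","))
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  V <- coords[uk, , drop = FALSE]
  F <- matrix(ids, ncol = 3, byrow = TRUE)
  surface_mesh(V, F)
}
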
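# Plain TIFF input/output for single-channel count images, channel
# manifests and run configuration files.
#
# Scope: baseline TIFF only - uncompressed, single image, one sample per
# pixel, uint16 or float32. That covers the per-channel exports produced
# by the standard MCD->TIFF conversion tools; anything fancier (RGB,
# multi-page stacks, compression) is rejected with a descriptive error.

.TIFF_TYPES <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)
.TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

#' Write a single-channel TIFF image
#'
#' Baseline little-endian TIFF: uncompressed, grayscale, single strip.
#' Count images default to 32-bit float since restored intensities are
#' real-valued; use `dtype = "uint16"` for raw integer counts in
#' `[0, 65535]`.
#'
#' @param img numeric matrix.
#' @param path output file path.
#' @param dtype `"float32"` or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, dtype = c("float32", "uint16")) {
  stopifnot(is.matrix(img))
  dtype <- match.arg(dtype)
  H <- nrow(img); W <- ncol(img)
  if (dtype == "uint16") {
    if (any(img < 0) || any(img > 65535) || any(img != round(img)))
      stop("uint16 output requires integer values in [0, 65535]",
           call. = FALSE)
    bps <- 16L; fmt <- 1L; bytes_px <- 2L
  } else {
    bps <- 32L; fmt <- 3L; bytes_px <- 4L
  }
  n_bytes <- H * W * bytes_px
  data_offset <- 8L
  ifd_offset <- data_offset + n_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  # pixel data, scanline (row-major) order
  v <- as.numeric(t(img))
  if (dtype == "uint16") {
    # writeBin has no unsigned 16-bit; values > 32767 wrap correctly
    iv <- as.integer(v)
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L
    writeBin(iv, con, size = 2, endian = "little")
  } else {
    writeBin(v, con, size = 4, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == .TIFF_TYPES[["SHORT"]]) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  tags <- list(
    list(256L, 4L, W), list(257L, 4L, H), list(258L, 3L, bps),
    list(259L, 3L, 1L), list(262L, 3L, 1L), list(273L, 4L, data_offset),
    list(277L, 3L, 1L), list(278L, 4L, H), list(279L, 4L, n_bytes),
    list(339L, 3L, fmt))
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) entry(tg[[1]], tg[[2]], 1L, tg[[3]])
  writeBin(0L, con, size = 4, endian = "little")  # no further IFD
  invisible(path)
}

#' Read a single-channel TIFF image
#'
#' Accepts uncompressed grayscale baseline TIFF (either byte order) with
#' 16-bit unsigned or 32-bit float samples, possibly split into several
#' strips. Multi-page and multi-sample (e.g. RGB) files raise an
#' unsupported-format error naming the offending layout.
#'
#' @param path TIFF file path.
#' @return numeric matrix (height x width).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8) stop("not a TIFF file", call. = FALSE)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM")
    "big" else stop("not a TIFF file (bad byte-order mark)", call. = FALSE)
  rd_int <- function(off, size, n = 1L) {
    # readBin only supports unsigned reads for sizes 1-2; 4-byte offsets
    # below 2^31 read correctly as signed
    readBin(raw_all[(off + 1L):(off + size * n)], "integer", n = n,
            size = size, signed = size >= 4L, endian = endian)
  }
  magic <- rd_int(2L, 2L)
  if (magic != 42L) stop("not a TIFF file (bad magic)", call. = FALSE)
  ifd_off <- rd_int(4L, 4L)
  n_entries <- rd_int(ifd_off, 2L)
  tags <- list()
  for (e in seq_len(n_entries)) {
    base <- ifd_off + 2L + (e - 1L) * 12L
    tag <- rd_int(base, 2L)
    type <- rd_int(base + 2L, 2L)
    count <- rd_int(base + 4L, 4L)
    tsz <- .TYPE_SIZE[type]
    payload <- count * tsz
    voff <- if (payload > 4L) rd_int(base + 8L, 4L) else base + 8L
    vals <- if (type %in% c(3L, 4L)) rd_int(voff, tsz, count) else NULL
    tags[[as.character(tag)]] <- vals
  }
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  next_ifd <- rd_int(ifd_off + 2L + n_entries * 12L, 4L)
  if (next_ifd != 0L)
    stop("unsupported TIFF layout: multi-page file", call. = FALSE)
  spp <- g(277L, 1L)
  if (spp != 1L)
    stop(sprintf(
      "unsupported TIFF layout: %d samples per pixel (e.g. RGB)", spp),
      call. = FALSE)
  if (g(259L, 1L) != 1L)
    stop("unsupported TIFF layout: compressed data", call. = FALSE)
  W <- g(256L); H <- g(257L)
  if (is.null(W) || is.null(H)) stop("TIFF missing dimensions", call. = FALSE)
  bps <- g(258L, 1L)
  fmt <- g(339L, 1L)
  strip_off <- g(273L)
  strip_len <- g(279L)
  if (is.null(strip_off)) stop("TIFF missing strip offsets", call. = FALSE)
  if (is.null(strip_len)) strip_len <- H * W * (bps / 8L)
  buf <- raw(0)
  for (s in seq_along(strip_off))
    buf <- c(buf, raw_all[(strip_off[s] + 1L):(strip_off[s] + strip_len[s])])
  n_px <- H * W
  if (bps == 16L && fmt %in% c(1L, NA)) {
    v <- readBin(buf, "integer", n = n_px, size = 2, signed = FALSE,
                 endian = endian)
  } else if (bps == 32L && fmt == 3L) {
    v <- readBin(buf, "double", n = n_px, size = 4, endian = endian)
  } else if (bps == 32L && fmt == 1L) {
    v <- readBin(buf, "integer", n = n_px, size = 4, endian = endian)
    if (any(v < 0)) stop("uint32 image exceeds integer range", call. = FALSE)
  } else {
    stop(sprintf(
      "unsupported TIFF layout: %d bits per sample, sample format %d",
      bps, fmt), call. = FALSE)
  }
  matrix(v, nrow = H, ncol = W, byrow = TRUE)
}

#' Read a channel manifest
#'
#' CSV with fixed header `file,channel,metal`, one row per marker image.
#' Paths are resolved relative to the manifest's directory when not
#' absolute; missing files and duplicate channel names are errors.
#'
#' @param path manifest CSV path.
#' @return data frame with columns `file`, `channel`, `metal`.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "channel", "metal")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: file, channel, metal", call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", df$file)
  df$file[rel] <- file.path(dirname(path), df$file[rel])
  if (anyDuplicated(df$channel))
    stop("duplicate channel names in manifest", call. = FALSE)
  missing <- !file.exists(df$file)
  if (any(missing))
    stop("manifest refers to missing file(s): ",
         paste(df$file[missing], collapse = ", "), call. = FALSE)
  df[, need]
}

# Default run configuration covering every pipeline stage.
default_run_config <- function() {
  list(
    dimr = list(n_iter = 3, l = 4, bg_cutoff = 4, round_output = FALSE),
    deepsnif = list(rho = 0.8, percentile = 99.99, lambda_hessian = 3e-6,
                    epochs = 200, batch_size = 128, lr = 0.001,
                    lr_decay = 0.6, lr_patience = 20, base_filters = 32,
                    masking_rate = 0.002, patch_size = 64, seed = 1,
                    skip = FALSE),
    simulate = list(size = 256, kind = "blobs", lambda_fg = 20,
                    lambda_bg = 1, hot_pixel_density = 0.01,
                    hot_cluster_density = 0, n = 10, seed = 1))
}

#' Load a run configuration from YAML
#'
#' Unknown keys (at the stage or parameter level) are rejected; omitted
#' parameters fall back to the defaults, so the load -> save -> load round
#' trip is stable.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(user)) {
    badk <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(badk))
      stop("unknown key(s) in section '", sec, "': ",
           paste(badk, collapse = ", "), call. = FALSE)
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg
}

#' Save a run configuration to YAML
#'
#' @param cfg configuration list as returned by [read_run_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
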
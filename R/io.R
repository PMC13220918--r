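#' Read a time-resolved image cube from HDF5
#'
#' Reads a photon-count cube stored in the package's HDF5 dialect (one 3-D
#' dataset plus `period_ns` / `bin_centers_ns` attributes and `meta:*` string
#' attributes). Third-party files with a different internal layout can be
#' ingested by overriding the `layout` entries: the dataset path, which axis
#' of the stored cube is time, and (if the file carries no period attribute)
#' the laser period itself.
#'
#' @param path HDF5 file path.
#' @param layout list with elements `dataset` (HDF5 path of the cube,
#'   default `"/counts"`), `time_axis_dim` (which stored dimension is time,
#'   1-3 in the file's own order, default 1), `period_attr` (name of the
#'   period attribute, default `"period_ns"`), and optional overrides
#'   `period_ns` and `bin_centers_ns` used when the file lacks the
#'   attributes.
#' @return An [fli_dataset()] with counts ordered `(time, row, col)`.
#' @export
read_dataset <- function(path, layout = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lay <- utils::modifyList(
    list(dataset = "/counts", time_axis_dim = 1L, period_attr = "period_ns",
         period_ns = NULL, bin_centers_ns = NULL),
    layout)
  raw <- .Call(C_h5_read, as.character(path), as.character(lay$dataset))
  d <- raw$dims                       # file (C) order
  rank <- length(d)
  if (rank == 1L) d <- c(d, 1L, 1L)
  if (rank == 2L) d <- c(d, 1L)
  # file C-order (d1,d2,d3) -> R array of dim (d1,d2,d3)
  cube <- aperm(array(raw$data, dim = rev(d)), 3:1)
  td <- as.integer(lay$time_axis_dim)
  if (td < 1L || td > 3L) stop("'time_axis_dim' must be 1, 2 or 3")
  cube <- aperm(cube, c(td, setdiff(1:3, td)))
  if (anyNA(cube) || any(cube < 0))
    stop("dataset contains negative or missing counts")

  attrs <- stats::setNames(raw$attr_values, raw$attr_names)
  period <- lay$period_ns
  if (is.null(period) && lay$period_attr %in% names(attrs))
    period <- as.numeric(attrs[[lay$period_attr]])[1]
  if (is.null(period))
    stop("no laser period: file lacks attribute '", lay$period_attr,
         "' and layout gives no 'period_ns' override")
  centers <- lay$bin_centers_ns
  if (is.null(centers) && "bin_centers_ns" %in% names(attrs))
    centers <- as.numeric(attrs[["bin_centers_ns"]])
  ax <- time_axis(dim(cube)[1], period_ns = period, bin_centers_ns = centers)

  meta_idx <- grep("^meta:", names(attrs))
  meta <- lapply(attrs[meta_idx], as.character)
  names(meta) <- sub("^meta:", "", names(attrs)[meta_idx])
  fli_dataset(cube, ax, meta = meta)
}

#' Write a time-resolved image cube to HDF5
#'
#' Inverse of [read_dataset()] for the package's own dialect: stores the
#' cube as a 3-D dataset in `(time, row, col)` order with `period_ns`,
#' `bin_centers_ns` and `meta:*` attributes.
#'
#' @param ds an [fli_dataset()].
#' @param path output file path (overwritten).
#' @param dataset HDF5 dataset path, default `"/counts"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, dataset = "/counts") {
  stopifnot(inherits(ds, "fli_dataset"))
  d <- dim(ds$counts)
  # R (time,row,col) column-major -> C-order (time,row,col) buffer
  buf <- as.double(aperm(ds$counts, c(3, 2, 1)))
  meta <- ds$meta
  .Call(C_h5_write, as.character(path), as.character(dataset),
        buf, as.integer(d),
        as.double(ds$time_axis$period_ns),
        as.double(ds$time_axis$bin_centers_ns),
        as.character(names(meta)),
        vapply(meta, function(v) paste(as.character(v), collapse = ";"),
               character(1)))
  invisible(path)
}

#' Read an integer label mask from TIFF
#'
#' Reads a single-plane label image of the kind exported by segmentation
#' tools (StarDist/Fiji): background 0, each object a distinct positive
#' integer. Float-valued storage is accepted only when every value is
#' integral.
#'
#' @param path TIFF file path.
#' @return Integer matrix of class `fli_label_mask` (`(row, col)`, 0 =
#'   background).
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- tiff::readTIFF(path, payload = FALSE)
  if (nrow(as.data.frame(info)) > 1L)
    stop("label mask must be a single-plane TIFF")
  # 8/16-bit TIFFs are integer samples; 32-bit ones are float samples whose
  # stored values must themselves be integral labels
  as_is <- info$bits.per.sample[1] < 32L
  planes <- tiff::readTIFF(path, as.is = as_is, all = TRUE)
  if (length(planes) != 1L)
    stop("label mask must be a single-plane TIFF; got ", length(planes),
         " planes")
  m <- planes[[1]]
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L) stop("label mask must have a single channel")
    m <- m[, , 1]
  }
  if (any(abs(m - round(m)) > 1e-9))
    stop("label mask contains non-integral values")
  m <- round(m)
  if (any(m < 0)) stop("label mask contains negative values")
  structure(matrix(as.integer(m), nrow(m), ncol(m)), class = "fli_label_mask")
}

#' Write an integer label mask to TIFF
#'
#' @param mask integer matrix (labels, 0 = background), values < 65536.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  m <- unclass(mask)
  if (any(m < 0) || any(m != round(m))) stop("labels must be non-negative integers")
  if (max(m) > 65535) stop("labels exceed 16-bit TIFF range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a decay curve from delimited text
#'
#' Accepts one numeric column (counts only; bin times then come from
#' `axis`) or two columns (time, counts), separated by commas, semicolons,
#' tabs or spaces. A single leading non-numeric header line is skipped.
#'
#' @param path text file path.
#' @param axis optional [time_axis()] supplying bin centers for
#'   counts-only files.
#' @return An [decay_curve()].
#' @export
read_decay_text <- function(path, axis = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty decay file: ", path)
  parse_line <- function(l) {
    suppressWarnings(as.numeric(strsplit(trimws(l), "[,;\t ]+")[[1]]))
  }
  rows <- lapply(lines, parse_line)
  bad <- vapply(rows, anyNA, logical(1))
  if (bad[1] && length(rows) > 1L) {    # header
    rows <- rows[-1]
    bad <- bad[-1]
  }
  if (any(bad))
    stop("non-numeric row(s) in decay file: ", path)
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L || !(ncols %in% 1:2))
    stop("decay file must have 1 or 2 numeric columns")
  m <- do.call(rbind, rows)
  if (ncols == 2L) return(decay_curve(m[, 1], m[, 2]))
  if (is.null(axis))
    stop("counts-only decay file needs a 'axis' to supply bin times")
  if (nrow(m) != axis$n_bins)
    stop("counts-only decay has ", nrow(m), " rows but axis has ",
         axis$n_bins, " bins")
  decay_curve(axis$bin_centers_ns, m[, 1])
}

#' Write a decay curve as two-column CSV text
#'
#' @param d an [decay_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decay_text <- function(d, path) {
  stopifnot(inherits(d, "fli_decay"))
  export_table(data.frame(time_ns = d$time_ns, counts = d$counts), path)
}

#' Export a rectangular table as CSV
#'
#' One header row, full double precision (15 significant digits), no row
#' names — suitable for re-import by third-party software.
#'
#' @param rows data frame or named list of equal-length numeric columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    lens <- vapply(rows, length, integer(1))
    if (length(unique(lens)) > 1L)
      stop("ragged columns: lengths ", paste(lens, collapse = ", "))
    rows <- as.data.frame(rows)
  }
  fmt <- lapply(rows, function(col) {
    if (is.numeric(col)) formatC(col, digits = 15, format = "g") else col
  })
  utils::write.csv(as.data.frame(fmt, optional = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- JSON sidecars ---------------------------------------------------------

sidecar_schema <- function(type) paste0("fliphasor/", type, "@1")

sidecar_type <- function(obj) {
  if (inherits(obj, "fli_calibration")) "calibration"
  else if (inherits(obj, "fli_reference_pair")) "reference_pair"
  else if (inherits(obj, "fli_roi_set")) "roi_set"
  else stop("no JSON sidecar defined for class ",
            paste(class(obj), collapse = "/"))
}

#' Save an analysis object as a JSON sidecar
#'
#' Lossless, versioned JSON persistence for phasor calibrations, reference
#' pairs and ROI sets, so an analysis can be re-run or audited later.
#'
#' @param obj a `fli_calibration`, `fli_reference_pair` or `fli_roi_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_json_sidecar <- function(obj, path) {
  type <- sidecar_type(obj)
  payload <- unclass(obj)
  if (type == "calibration")
    payload$phasor <- unclass(payload$phasor)
  if (type == "reference_pair") {
    payload$p1 <- unclass(payload$p1)
    payload$p2 <- unclass(payload$p2)
  }
  if (type == "roi_set")
    payload$rois <- lapply(payload$rois, function(r) {
      r$pixels <- unname(r$pixels)
      r
    })
  jsonlite::write_json(list(schema = sidecar_schema(type), payload = payload),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a JSON sidecar written by [save_json_sidecar()]
#'
#' @param path JSON file path.
#' @return The restored object, with its original class.
#' @export
load_json_sidecar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("corrupted sidecar: ",
                                           conditionMessage(e)))
  if (is.null(obj$schema) || is.null(obj$payload))
    stop("not a fliphasor sidecar: ", path)
  m <- regmatches(obj$schema,
                  regexec("^fliphasor/([a-z_]+)@([0-9]+)$", obj$schema))[[1]]
  if (length(m) != 3L) stop("unrecognized sidecar schema: ", obj$schema)
  type <- m[2]
  if (m[3] != "1")
    stop("sidecar schema version ", m[3], " not supported (expected 1)")
  p <- obj$payload
  switch(type,
    calibration = {
      ph <- p$phasor
      if (identical(p$mode, "per_pixel")) {
        pim <- phasor_image_new(as.matrix(ph$g), as.matrix(ph$s),
                                valid = matrix(TRUE, nrow(as.matrix(ph$g)),
                                               ncol(as.matrix(ph$g))),
                                harmonic = ph$harmonic,
                                frequency_MHz = ph$frequency_MHz)
        phasor_calibration(pim, p$reference_lifetime_ns, mode = "per_pixel")
      } else {
        phasor_calibration(phasor(ph$g, ph$s, ph$harmonic, ph$frequency_MHz),
                           p$reference_lifetime_ns)
      }
    },
    reference_pair = {
      rp <- reference_pair(
        phasor(p$p1$g, p$p1$s, p$p1$harmonic, p$p1$frequency_MHz),
        phasor(p$p2$g, p$p2$s, p$p2$harmonic, p$p2$frequency_MHz),
        p$tau1_ns, p$tau2_ns)
      rp$message <- p$message
      rp
    },
    roi_set = {
      rois <- lapply(seq_along(p$rois$id), function(i) {
        px <- p$rois$pixels[[i]]
        list(id = as.integer(p$rois$id[[i]]),
             pixels = matrix(as.integer(px), ncol = 2,
                             dimnames = list(NULL, c("row", "col"))),
             name = if (!is.null(p$rois$name)) p$rois$name[[i]] else NULL)
      })
      roi_set(rois, shape = as.integer(p$shape))
    },
    stop("unrecognized sidecar type: ", type))
}
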
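#' Region-of-interest set
#'
#' An ordered collection of labelled pixel sets over an image grid. Pixel
#' coordinates are 0-based `(row, col)` with row 0 at the top, matching the
#' raster order of a label-mask TIFF. ROIs may overlap; ids are unique.
#'
#' @param rois list of ROIs, each a list with `id` (integer), `pixels`
#'   (n x 2 integer matrix, columns `row`, `col`, 0-based) and optional
#'   `name`.
#' @param shape integer `c(rows, cols)` of the host image.
#' @return An object of class `fli_roi_set`.
#' @export
roi_set <- function(rois, shape) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) stop("'shape' must be (rows, cols)")
  ids <- vapply(rois, function(r) as.integer(r$id), integer(1))
  if (anyDuplicated(ids)) stop("ROI ids must be unique")
  for (r in rois) {
    px <- r$pixels
    if (!is.matrix(px) || ncol(px) != 2L || nrow(px) < 1L)
      stop("each ROI needs a non-empty n x 2 pixel matrix")
    if (any(px < 0L) || any(px[, 1] >= shape[1]) || any(px[, 2] >= shape[2]))
      stop("ROI ", r$id, " has pixels outside the image grid")
  }
  structure(list(rois = rois, shape = shape), class = "fli_roi_set")
}

#' @export
print.fli_roi_set <- function(x, ...) {
  sizes <- vapply(x$rois, function(r) nrow(r$pixels), integer(1))
  cat(sprintf("<fli_roi_set> %d ROIs on a %d x %d grid (%s pixels)\n",
              length(x$rois), x$shape[1], x$shape[2],
              if (length(sizes)) paste(range(sizes), collapse = "-") else "0"))
  invisible(x)
}

#' @export
length.fli_roi_set <- function(x) length(x$rois)

roi_ids <- function(rs) vapply(rs$rois, function(r) r$id, integer(1))

roi_by_id <- function(rs, id) {
  i <- match(id, roi_ids(rs))
  if (is.na(i)) stop("no ROI with id ", id)
  rs$rois[[i]]
}

#' ROIs from an integer label mask
#'
#' One ROI per distinct non-zero label (segmentation-tool export style);
#' ROI id = label value, ordered by label. An all-zero mask yields an empty
#' set.
#'
#' @param mask an `fli_label_mask` (or integer matrix).
#' @return An [roi_set()].
#' @export
rois_from_labels <- function(mask) {
  m <- unclass(mask)
  stopifnot(is.matrix(m))
  labs <- sort(unique(as.integer(m[m > 0])))
  rois <- lapply(labs, function(l) {
    idx <- which(m == l, arr.ind = TRUE)
    list(id = as.integer(l),
         pixels = cbind(row = as.integer(idx[, 1] - 1L),
                        col = as.integer(idx[, 2] - 1L)))
  })
  roi_set(rois, shape = dim(m))
}

#' Render a non-overlapping ROI set as a label mask
#'
#' Inverse of [rois_from_labels()] for non-overlapping sets.
#'
#' @param rs an [roi_set()].
#' @return An `fli_label_mask` matrix.
#' @export
rois_to_labels <- function(rs) {
  stopifnot(inherits(rs, "fli_roi_set"))
  m <- matrix(0L, rs$shape[1], rs$shape[2])
  for (r in rs$rois) {
    idx <- r$pixels[, 1] + 1L + rs$shape[1] * r$pixels[, 2]
    if (any(m[idx] != 0L)) stop("overlapping ROIs cannot be rendered as labels")
    m[idx] <- r$id
  }
  structure(m, class = "fli_label_mask")
}

#' ROIs from an intensity threshold
#'
#' Connected components of the set of pixels whose total count reaches
#' `min_counts`, under 4- or 8-connectivity; one ROI per component, ids
#' assigned 1..n in raster order of each component's first pixel.
#' `per_component = FALSE` instead returns all supra-threshold pixels as a
#' single ROI.
#'
#' @param ds an [fli_dataset()].
#' @param min_counts intensity threshold.
#' @param connectivity 4 or 8 (default 8, the usual blob convention for
#'   cell masks).
#' @param per_component split into connected components (default TRUE).
#' @return An [roi_set()] (possibly empty).
#' @export
rois_from_threshold <- function(ds, min_counts, connectivity = 8,
                                per_component = TRUE) {
  stopifnot(inherits(ds, "fli_dataset"))
  if (!connectivity %in% c(4, 8)) stop("'connectivity' must be 4 or 8")
  img <- intensity_image(ds)
  sel <- which(img >= min_counts)
  shape <- dim(img)
  if (!length(sel)) return(roi_set(list(), shape))
  rc <- arrayInd(sel, shape)           # 1-based
  if (!per_component) {
    return(roi_set(list(list(
      id = 1L, pixels = cbind(row = rc[, 1] - 1L, col = rc[, 2] - 1L))),
      shape))
  }
  comp <- label_components(sel, shape, connectivity)
  rois <- lapply(seq_len(max(comp)), function(ci) {
    px <- rc[comp == ci, , drop = FALSE]
    list(id = ci, pixels = cbind(row = px[, 1] - 1L, col = px[, 2] - 1L))
  })
  roi_set(rois, shape)
}

# Connected components of a pixel subset via the adjacency graph.
# sel: linear (column-major) indices of foreground pixels; returns component
# id per pixel, numbered in raster order (row-major) of first appearance.
label_components <- function(sel, shape, connectivity) {
  nr <- shape[1]
  pos <- integer(prod(shape))
  pos[sel] <- seq_along(sel)
  r <- (sel - 1L) %% nr
  c <- (sel - 1L) %/% nr
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (o in offs) {
    rr <- r + o[1]; cc <- c + o[2]
    ok <- rr >= 0L & rr < nr & cc >= 0L & cc < shape[2]
    nb <- rr[ok] + 1L + nr * cc[ok]
    has <- pos[nb] > 0L
    edges <- c(edges, rbind(pos[sel[ok]][has], pos[nb][has]))
  }
  g <- igraph::make_graph(edges = edges, n = length(sel), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber in raster (row-major) order of first appearance
  ord <- order(r, c)
  first <- memb[ord][!duplicated(memb[ord])]
  match(memb, first)
}

#' Regular grid of rectangular ROIs
#'
#' Tiles the image with `h x w` cells; partial edge cells are kept. Ids run
#' in row-major order of the grid.
#'
#' @param shape integer `c(rows, cols)`.
#' @param cell integer `c(h, w)`, both >= 1.
#' @return An [roi_set()].
#' @export
roi_grid <- function(shape, cell) {
  shape <- as.integer(shape); cell <- as.integer(cell)
  if (any(cell < 1L)) stop("cell dims must be >= 1")
  r0 <- seq(0L, shape[1] - 1L, by = cell[1])
  c0 <- seq(0L, shape[2] - 1L, by = cell[2])
  rois <- list()
  id <- 0L
  for (r in r0) for (cc in c0) {
    id <- id + 1L
    rows <- r:min(r + cell[1] - 1L, shape[1] - 1L)
    cols <- cc:min(cc + cell[2] - 1L, shape[2] - 1L)
    px <- as.matrix(expand.grid(row = rows, col = cols))
    rois[[id]] <- list(id = id, pixels = cbind(row = as.integer(px[, 1]),
                                               col = as.integer(px[, 2])))
  }
  roi_set(rois, shape)
}

#' Merge ROIs into one
#'
#' Replaces the named ROIs by a single ROI whose pixel set is their union;
#' the merged ROI keeps the smallest of the merged ids and takes the
#' position of its first member.
#'
#' @param rs an [roi_set()].
#' @param ids ids to merge (all must exist).
#' @return An [roi_set()].
#' @export
merge_rois <- function(rs, ids) {
  stopifnot(inherits(rs, "fli_roi_set"))
  all_ids <- roi_ids(rs)
  if (!all(ids %in% all_ids))
    stop("unknown ROI id(s): ", paste(setdiff(ids, all_ids), collapse = ", "))
  if (length(ids) < 2L) return(rs)
  sel <- all_ids %in% ids
  px <- do.call(rbind, lapply(rs$rois[sel], function(r) r$pixels))
  px <- unique(px)
  merged <- list(id = as.integer(min(ids)), pixels = px)
  keep <- rs$rois[!sel]
  pos <- which(sel)[1]
  out <- append(keep, list(merged), after = pos - 1L)
  roi_set(out, rs$shape)
}

#' Explode an ROI into single-pixel ROIs
#'
#' Replaces one ROI by one ROI per member pixel (for pixel-wise analysis of
#' a region). New ids continue past the current maximum.
#'
#' @param rs an [roi_set()].
#' @param id id of the ROI to explode.
#' @return An [roi_set()].
#' @export
explode_to_pixels <- function(rs, id) {
  stopifnot(inherits(rs, "fli_roi_set"))
  all_ids <- roi_ids(rs)
  i <- match(id, all_ids)
  if (is.na(i)) stop("no ROI with id ", id)
  px <- rs$rois[[i]]$pixels
  next_id <- max(all_ids)
  singles <- lapply(seq_len(nrow(px)), function(j) {
    list(id = as.integer(next_id + j),
         pixels = px[j, , drop = FALSE])
  })
  if (nrow(px) == 1L) singles[[1]]$id <- as.integer(id)
  roi_set(append(rs$rois[-i], singles, after = i - 1L), rs$shape)
}

#' Aggregated decay of an ROI
#'
#' Sums the per-pixel decays over the ROI's pixels (the standard way to
#' boost counting statistics before a fit or phasor).
#'
#' @param ds an [fli_dataset()].
#' @param roi a single ROI (element of an [roi_set()]'s `rois`), or an id
#'   together with `rs`.
#' @param rs optional [roi_set()] when `roi` is given as an id.
#' @return An [decay_curve()] on the dataset's bin centers.
#' @export
roi_decay <- function(ds, roi, rs = NULL) {
  stopifnot(inherits(ds, "fli_dataset"))
  if (!is.list(roi)) roi <- roi_by_id(rs, roi)
  d <- dim(ds$counts)
  if (any(roi$pixels[, 1] >= d[2]) || any(roi$pixels[, 2] >= d[3]))
    stop("ROI pixels outside the dataset")
  nt <- d[1]
  flat <- matrix(ds$counts, nrow = nt)
  pix_idx <- roi$pixels[, 1] + 1L + d[2] * roi$pixels[, 2]
  counts <- rowSums(flat[, pix_idx, drop = FALSE])
  decay_curve(ds$time_axis$bin_centers_ns, counts)
}
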
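#' Place circular ROIs inside a liver mask
#'
#' Mirrors the reading protocol of the staging study: a fixed number of
#' small, roughly circular regions of interest (about 3-4 mm^2 each) placed
#' away from the liver margin. The mask is eroded by one pixel
#' (8-neighbourhood) so every ROI pixel lies at least one pixel inside the
#' boundary, ROIs are pairwise disjoint and connected, and placement is
#' reproducible from the seed.
#'
#' @param mask Logical matrix; `TRUE` marks liver pixels.
#' @param pixel_size_mm In-plane pixel size, mm.
#' @param n_rois Number of ROIs to place.
#' @param area_range_mm2 Length-2 numeric: admissible ROI area in mm^2.
#' @param seed Integer seed for reproducible placement.
#' @return An object of class `roi_set`: a list with `rois` (list of
#'   integer matrices of pixel row/col indices), `areas_mm2`, and
#'   `pixel_size_mm`.
#' @export
place_rois <- function(mask, pixel_size_mm, n_rois = 5L,
                       area_range_mm2 = c(3, 4), seed = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask), pixel_size_mm > 0,
            n_rois >= 1L, length(area_range_mm2) == 2L,
            area_range_mm2[1] <= area_range_mm2[2])
  if (!is.null(seed)) set.seed(seed)
  px_area <- pixel_size_mm^2
  k_min <- ceiling(area_range_mm2[1] / px_area)
  k_max <- floor(area_range_mm2[2] / px_area)
  if (k_max < k_min) k_max <- k_min  # coarse pixels: take the smallest size over the range
  interior <- erode_mask(mask)
  if (sum(interior) < n_rois * k_min) {
    stop(sprintf(paste0("cannot place %d ROIs of >= %d pixels: only %d ",
                        "interior (margin-eroded) mask pixels available"),
                 n_rois, k_min, sum(interior)), call. = FALSE)
  }
  free <- interior
  rois <- vector("list", n_rois)
  max_attempts <- 200L
  for (r in seq_len(n_rois)) {
    k <- if (k_max > k_min) sample(k_min:k_max, 1L) else k_min
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      avail <- which(free)
      if (length(avail) < k) break
      ctr <- avail[sample.int(length(avail), 1L)]
      blob <- grow_blob(free, ctr, k)
      if (!is.null(blob)) {
        free[blob] <- FALSE
        rois[[r]] <- which_rc(blob, nrow(mask))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("could not place ROI %d of %d after %d attempts: ",
                          "remaining interior pixels too fragmented for a ",
                          "connected %d-pixel region"),
                   r, n_rois, max_attempts, k), call. = FALSE)
    }
  }
  structure(list(rois = rois,
                 areas_mm2 = vapply(rois, nrow, 1L) * px_area,
                 pixel_size_mm = pixel_size_mm),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>", length(x$rois), "ROIs,",
      paste(sprintf("%.1f", x$areas_mm2), collapse = "/"), "mm^2\n")
  invisible(x)
}

# 8-neighbourhood erosion: keep pixels whose full neighbourhood is in-mask
erode_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- mask
  for (di in -1:1) for (dj in -1:1) {
    out <- out & padded[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  out
}

# k nearest free pixels around a centre, accepted only if 4-connected
grow_blob <- function(free, ctr, k) {
  nr <- nrow(free)
  avail <- which(free)
  ci <- (ctr - 1L) %% nr + 1L
  cj <- (ctr - 1L) %/% nr + 1L
  ai <- (avail - 1L) %% nr + 1L
  aj <- (avail - 1L) %/% nr + 1L
  d2 <- (ai - ci)^2 + (aj - cj)^2
  ord <- order(d2, avail)  # deterministic tie-break by linear index
  if (length(ord) < k) return(NULL)
  blob <- avail[ord[seq_len(k)]]
  if (!is_connected(blob, nr)) return(NULL)
  blob
}

is_connected <- function(pixels, nr) {
  if (length(pixels) <= 1L) return(TRUE)
  ri <- (pixels - 1L) %% nr + 1L
  cj <- (pixels - 1L) %/% nr + 1L
  seen <- logical(length(pixels))
  seen[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    q <- queue[1]; queue <- queue[-1]
    adj <- abs(ri - ri[q]) + abs(cj - cj[q]) == 1L
    hit <- which(!seen & adj)
    seen[hit] <- TRUE
    queue <- c(queue, hit)
  }
  all(seen)
}

which_rc <- function(linear, nr) {
  cbind(row = (linear - 1L) %% nr + 1L, col = (linear - 1L) %/% nr + 1L)
}

#' Summarize a subject's parameter maps over its ROIs
#'
#' Each parameter's summary value is the mean over the union of all ROI
#' pixels (equivalently, the ROI-size-weighted mean of per-ROI means).
#' Pixels whose fit did not converge are excluded from the mean and counted.
#'
#' @param maps A `parameter_maps` object from [fit_volume()], or a list of
#'   several (e.g. mono + DKI + SEM maps of the same subject); their
#'   parameter maps are combined into one summary row.
#' @param rois An `roi_set` from [place_rois()].
#' @param meta Named list of subject metadata carried through to the output
#'   (e.g. `subject_id`, `stage`, `collagen`).
#' @return One-row data frame with the metadata columns followed by the mean
#'   of every available parameter map (diffusion coefficients in mm^2/s),
#'   with attribute `n_excluded` = number of non-converged ROI pixels.
#' @export
summarize_subject <- function(maps, rois, meta = list()) {
  stopifnot(inherits(rois, "roi_set"))
  if (inherits(maps, "parameter_maps")) maps <- list(maps)
  stopifnot(all(vapply(maps, inherits, TRUE, "parameter_maps")))
  px <- do.call(rbind, rois$rois)
  out <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(out) == 0L) out <- data.frame(row.names = 1L)
  n_excluded <- 0L
  par_names <- c("ADC", "D_app", "K_app", "DDC", "alpha")
  for (m in maps) {
    conv <- m$converged[px]
    ok <- !is.na(conv) & conv
    if (!any(ok)) {
      stop("all ROI pixels are non-converged for the ", m$model, " maps",
           call. = FALSE)
    }
    n_excluded <- n_excluded + sum(!ok)
    for (p in intersect(par_names, names(m))) {
      out[[p]] <- mean(m[[p]][px][ok])
    }
  }
  attr(out, "n_excluded") <- n_excluded
  out
}
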
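#' Segmentation parameters
#'
#' Defaults reproduce the DAPI operator chain used for tumor-section
#' immunofluorescence: a one-sided Gaussian low-pass background removal
#' (sd 40 px), saturation at the 95th intensity percentile, binarization at
#' 0.40 of the normalized dynamic range, and removal of objects smaller than
#' 20 px. The analysis region around each nucleus is the nucleus dilated by
#' `analysis_dilation_px` (Euclidean), with contested pixels assigned to the
#' nucleus with the nearest centroid.
#'
#' @param background_sigma Gaussian background kernel sd, pixels (> 0).
#' @param saturation_percentile percentile (0-100] at which intensities are
#'   capped before normalization.
#' @param binarize_fraction threshold on the normalized `[0, 1]` range,
#'   in (0, 1).
#' @param min_object_px objects with fewer pixels are discarded (>= 1).
#' @param analysis_dilation_px dilation radius of the per-cell analysis
#'   region, pixels (>= 0).
#' @param connectivity connected-component connectivity, 4 or 8.
#' @return a list of class `seg_params`.
#' @export
seg_params <- function(background_sigma = 40,
                       saturation_percentile = 95,
                       binarize_fraction = 0.40,
                       min_object_px = 20,
                       analysis_dilation_px = 5,
                       connectivity = 8) {
  stopifnot(background_sigma > 0,
            saturation_percentile > 0, saturation_percentile <= 100,
            binarize_fraction > 0, binarize_fraction < 1,
            min_object_px >= 1, analysis_dilation_px >= 0,
            connectivity %in% c(4, 8))
  structure(list(background_sigma = background_sigma,
                 saturation_percentile = saturation_percentile,
                 binarize_fraction = binarize_fraction,
                 min_object_px = min_object_px,
                 analysis_dilation_px = analysis_dilation_px,
                 connectivity = connectivity),
            class = "seg_params")
}

#' Remove low-frequency background from a fluorescence channel
#'
#' One-sided low-pass correction: the background estimate is a wide Gaussian
#' blur of the image itself; it is subtracted and negative residuals are
#' clipped at zero, so the output is nonnegative with the smooth field
#' removed.
#'
#' @param img numeric matrix of nonnegative intensities.
#' @param sigma Gaussian kernel standard deviation, pixels (> 0).
#' @return matrix of the same shape, nonnegative.
#' @export
subtract_background <- function(img, sigma = 40) {
  check_channel(img, "img")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a positive scalar")
  # cap the kernel support so it never exceeds the image (small fields)
  r <- 2 * ceiling(3 * sigma) + 1
  mx <- min(dim(img))
  if (r > mx) r <- mx - ((mx + 1) %% 2)  # largest odd size that fits
  bg <- as.matrix(EBImage::gblur(img, sigma = sigma, radius = r))
  pmax(img - bg, 0)
}

#' Saturate at a percentile and rescale to the normalized dynamic range
#'
#' Values above the given percentile of the image intensities (computed over
#' all pixels of the channel) are set to that percentile; the result is then
#' min-max rescaled to `[0, 1]`. A constant (zero dynamic range) input maps
#' to all zeros.
#'
#' @param img numeric matrix.
#' @param percentile percent in (0, 100].
#' @return matrix with values in `[0, 1]`.
#' @export
saturate_normalize <- function(img, percentile = 95) {
  check_channel(img, "img", allow_negative = TRUE)
  stopifnot(percentile > 0, percentile <= 100)
  q <- as.numeric(quantile(img, percentile / 100, names = FALSE))
  img[img > q] <- q
  lo <- min(img)
  if (q - lo <= 0) return(matrix(0, nrow(img), ncol(img)))
  (img - lo) / (q - lo)
}

#' Binarize a normalized channel at a fraction of the dynamic range
#'
#' @param img numeric matrix, expected in `[0, 1]`.
#' @param fraction threshold in (0, 1); pixels with value `>= fraction` are
#'   foreground.
#' @return logical matrix.
#' @export
binarize <- function(img, fraction = 0.40) {
  check_channel(img, "img", allow_negative = TRUE)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  img >= fraction
}

#' Index nuclei by connected components and filter small objects
#'
#' @param mask logical matrix.
#' @param min_object_px components with area `< min_object_px` are removed.
#' @param connectivity 4 or 8 (default 8).
#' @return a `nuclei_seg` object with fields `label_image` (consecutive
#'   positive integer labels, 0 background), `analysis_region` (initially
#'   equal to the nuclei), `n_cells`, `areas`, `centroids`.
#' @export
label_nuclei <- function(mask, min_object_px = 20, connectivity = 8) {
  stopifnot(is.matrix(mask), min_object_px >= 1)
  lab <- label_components(mask, connectivity)
  areas <- label_areas(lab)
  lab <- drop_labels(lab, which(areas < min_object_px))
  areas <- label_areas(lab)
  structure(list(label_image = lab,
                 analysis_region = lab,
                 n_cells = max(lab),
                 areas = areas,
                 centroids = label_centroids(lab),
                 params = NULL),
            class = "nuclei_seg")
}

#' @export
print.nuclei_seg <- function(x, ...) {
  cat("Nuclei segmentation:", x$n_cells, "cells on a",
      paste(dim(x$label_image), collapse = " x "), "px field\n")
  if (x$n_cells > 0)
    cat("  nucleus area (px): median", stats::median(x$areas),
        " range", paste(range(x$areas), collapse = "-"), "\n")
  invisible(x)
}

#' Grow per-cell analysis regions around segmented nuclei
#'
#' Each nucleus is dilated by `dilation_px` (Euclidean distance transform).
#' Pixels claimed by more than one nucleus are assigned to the nucleus with
#' the nearest centroid; exact ties go to the lower cell id. Every analysis
#' region is a superset of its nucleus.
#'
#' @param seg a `nuclei_seg` object.
#' @param dilation_px dilation radius in pixels (>= 0).
#' @return `seg` with its `analysis_region` field replaced.
#' @export
build_analysis_region <- function(seg, dilation_px = 5) {
  stopifnot(inherits(seg, "nuclei_seg"))
  if (!is.numeric(dilation_px) || length(dilation_px) != 1 || dilation_px < 0)
    stop("dilation_px must be >= 0")
  lab <- seg$label_image
  if (seg$n_cells == 0 || dilation_px == 0) {
    seg$analysis_region <- lab
    return(seg)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- ceiling(dilation_px) + 1L
  region <- lab
  claim_idx <- integer(0); claim_lab <- integer(0)
  for (id in seq_len(seg$n_cells)) {
    w <- which(lab == id)
    r <- ((w - 1L) %% nr) + 1L
    cc <- ((w - 1L) %/% nr) + 1L
    r0 <- max(1L, min(r) - pad); r1 <- min(nr, max(r) + pad)
    c0 <- max(1L, min(cc) - pad); c1 <- min(nc, max(cc) + pad)
    sub <- matrix(1, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(r - r0 + 1L, cc - c0 + 1L)] <- 0
    d <- as.matrix(EBImage::distmap(sub))
    sel <- which(d <= dilation_px & sub > 0)  # dilation ring, nucleus excluded
    if (length(sel)) {
      sr <- ((sel - 1L) %% nrow(sub)) + r0
      sc <- ((sel - 1L) %/% nrow(sub)) + c0
      claim_idx <- c(claim_idx, (sc - 1L) * nr + sr)
      claim_lab <- c(claim_lab, rep.int(id, length(sel)))
    }
  }
  # drop claims over other nuclei (regions never overwrite nucleus pixels)
  keep <- lab[claim_idx] == 0L
  claim_idx <- claim_idx[keep]; claim_lab <- claim_lab[keep]
  if (length(claim_idx)) {
    dup <- claim_idx %in% claim_idx[duplicated(claim_idx)]
    region[claim_idx[!dup]] <- claim_lab[!dup]
    if (any(dup)) {
      ci <- claim_idx[dup]; cl <- claim_lab[dup]
      pr <- ((ci - 1L) %% nr) + 1L
      pc <- ((ci - 1L) %/% nr) + 1L
      d2 <- (seg$centroids[cl, 1] - pr)^2 + (seg$centroids[cl, 2] - pc)^2
      o <- order(ci, d2, cl)  # per pixel: nearest centroid, ties to lower id
      first <- !duplicated(ci[o])
      region[ci[o][first]] <- cl[o][first]
    }
  }
  seg$analysis_region <- region
  seg
}

#' Segment nuclei from a raw DAPI channel
#'
#' Full operator chain: [subtract_background()], [saturate_normalize()],
#' [binarize()], [label_nuclei()], [build_analysis_region()]. The chain is
#' gain-invariant: multiplying the raw image by a positive constant leaves
#' the mask unchanged.
#'
#' @param dapi raw DAPI channel, numeric matrix of nonnegative intensities.
#' @param params a [seg_params()] object.
#' @return a `nuclei_seg` object.
#' @export
segment_nuclei <- function(dapi, params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  x <- subtract_background(dapi, params$background_sigma)
  x <- saturate_normalize(x, params$saturation_percentile)
  m <- binarize(x, params$binarize_fraction)
  seg <- label_nuclei(m, params$min_object_px, params$connectivity)
  seg <- build_analysis_region(seg, params$analysis_dilation_px)
  seg$params <- params
  seg
}

#' Mean marker intensity per cell over the analysis region
#'
#' The marker channel must already be background-subtracted (see
#' [subtract_background()]); no normalization is applied so that per-cell
#' means stay on the linear intensity scale and group ratios are meaningful.
#' The slide-level statistic is the unweighted mean of per-cell means.
#'
#' @param seg a `nuclei_seg` object with analysis regions built.
#' @param marker background-subtracted marker channel, same shape as the
#'   segmentation.
#' @param channel_name label stored in the output.
#' @return list with `cells` (data.frame: cell_id, nucleus_area,
#'   region_area, marker_mean) and `slide_mean` (`NA` when there are no
#'   cells).
#' @export
quantify_cells <- function(seg, marker, channel_name = "marker") {
  stopifnot(inherits(seg, "nuclei_seg"))
  check_channel(marker, "marker")
  if (!all(dim(marker) == dim(seg$label_image)))
    stop("marker and segmentation shapes differ")
  if (seg$n_cells == 0) {
    return(list(cells = data.frame(cell_id = integer(0),
                                   nucleus_area = integer(0),
                                   region_area = integer(0),
                                   marker_mean = numeric(0)),
                slide_mean = NA_real_, channel = channel_name))
  }
  reg <- seg$analysis_region
  idx <- which(reg > 0L)
  sums <- rowsum(marker[idx], reg[idx])
  cnts <- tabulate(reg[idx], nbins = seg$n_cells)
  means <- as.numeric(sums) / cnts
  cells <- data.frame(cell_id = seq_len(seg$n_cells),
                      nucleus_area = seg$areas,
                      region_area = cnts,
                      marker_mean = means)
  list(cells = cells, slide_mean = mean(means), channel = channel_name)
}

#' Fold change between treated and control slide means
#'
#' Ratio of group means of slide-level marker intensities, plus per-slide
#' ratios to the control mean for dispersion reporting.
#'
#' @param treated,control numeric vectors of slide-level means (>= 1 value
#'   each; control mean must be > 0).
#' @return list with `fold_change` (ratio of group means), `treated_mean`,
#'   `control_mean`, `per_slide` (treated slide / control mean).
#' @export
fold_change <- function(treated, control) {
  if (!length(treated) || !length(control))
    stop("both groups need at least one slide mean")
  if (anyNA(treated) || anyNA(control)) stop("slide means contain NA")
  cm <- mean(control)
  if (cm <= 0) stop("control mean must be > 0")
  list(fold_change = mean(treated) / cm,
       treated_mean = mean(treated), control_mean = cm,
       per_slide = treated / cm)
}

#' Match segmented nuclei to planted ground truth
#'
#' A planted nucleus is recovered when its center pixel falls inside a
#' segmented nucleus; each segmented label matches at most one planted
#' nucleus. Reports recall, precision and the raw counts.
#'
#' @param seg a `nuclei_seg` object.
#' @param truth an [image_truth()] object (or a matrix of centers).
#' @return list with `tp`, `fn`, `fp`, `recall`, `precision`.
#' @export
match_nuclei <- function(seg, truth) {
  centers <- if (inherits(truth, "image_truth")) truth$centers else truth
  lab <- seg$label_image
  hit <- lab[cbind(pmin(pmax(round(centers[, 1]), 1), nrow(lab)),
                   pmin(pmax(round(centers[, 2]), 1), ncol(lab)))]
  tp <- length(unique(hit[hit > 0L]))  # a merged label counts once
  fp <- seg$n_cells - tp
  fn <- nrow(centers) - tp
  list(tp = tp, fn = fn, fp = fp,
       recall = if (nrow(centers)) tp / nrow(centers) else NA_real_,
       precision = if (seg$n_cells) tp / seg$n_cells else NA_real_)
}
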
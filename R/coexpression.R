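#' Positivity parameters for dual-marker counting
#'
#' Defaults follow the Treg (CD3+/FOXP3+) tissue analysis: marker channels
#' are binarized at 0.2 (TxRed/FOXP3) and 0.3 (GFP/CD3) of the normalized
#' dynamic range, and surviving marker objects must have 20-500 px.
#'
#' @param threshold_a,threshold_b binarization thresholds in (0, 1) for the
#'   two marker channels.
#' @param min_object_px,max_object_px object-size window in pixels
#'   (`min < max`).
#' @param min_overlap_px minimum pixel overlap between a marker object and a
#'   cell's nucleus-or-cytoplasm region for a positive call (default 1).
#' @return a list of class `positivity_params`.
#' @export
positivity_params <- function(threshold_a = 0.3, threshold_b = 0.2,
                              min_object_px = 20, max_object_px = 500,
                              min_overlap_px = 1) {
  stopifnot(threshold_a > 0, threshold_a < 1,
            threshold_b > 0, threshold_b < 1,
            min_object_px >= 1, min_object_px < max_object_px,
            min_overlap_px >= 1)
  structure(list(threshold_a = threshold_a, threshold_b = threshold_b,
                 min_object_px = min_object_px, max_object_px = max_object_px,
                 min_overlap_px = min_overlap_px),
            class = "positivity_params")
}

#' Size-filtered marker objects restricted to cell regions
#'
#' The marker channel must already be background-subtracted and
#' saturated/normalized with the same chain as DAPI (see
#' [subtract_background()], [saturate_normalize()]; [count_double_positive()]
#' applies the full chain). It is binarized at `threshold`; masked pixels
#' that overlap neither a nucleus nor the perinuclear cytoplasm (the
#' analysis region) are removed before connected-component indexing, and
#' objects outside the `[min_object_px, max_object_px]` window are dropped.
#'
#' @param marker normalized marker channel (numeric matrix in `[0, 1]`).
#' @param threshold binarization threshold in (0, 1) on the normalized
#'   range.
#' @param seg a `nuclei_seg` object (from [segment_nuclei()]) whose analysis
#'   region defines nucleus + cytoplasm.
#' @param params a [positivity_params()] object (size window).
#' @param connectivity connected-component connectivity, 4 or 8.
#' @return integer label matrix of surviving marker objects.
#' @export
marker_objects <- function(marker, threshold, seg,
                           params = positivity_params(),
                           connectivity = 8) {
  stopifnot(inherits(seg, "nuclei_seg"), inherits(params, "positivity_params"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  if (!all(dim(marker) == dim(seg$label_image)))
    stop("marker and segmentation shapes differ")
  m <- marker >= threshold
  m[seg$analysis_region == 0L] <- FALSE  # neither nuclei nor cytoplasm
  lab <- label_components(m, connectivity)
  areas <- label_areas(lab)
  drop_labels(lab, which(areas < params$min_object_px |
                         areas > params$max_object_px))
}

#' Single- and double-positive cell calls from two marker channels
#'
#' A cell is positive for a channel when at least one surviving marker
#' object overlaps its nucleus or cytoplasm (analysis region) by at least
#' `min_overlap_px` pixels; cells positive in both channels are double
#' positive.
#'
#' @param seg a `nuclei_seg` object.
#' @param objects_a,objects_b label matrices from [marker_objects()] for the
#'   two channels.
#' @param min_overlap_px minimum shared pixels for a positive call.
#' @return list with `calls` (data.frame: cell_id, positive_a, positive_b,
#'   double_positive) and `counts` (named: n_cells, a_positive, b_positive,
#'   double_positive).
#' @export
call_positivity <- function(seg, objects_a, objects_b, min_overlap_px = 1) {
  stopifnot(inherits(seg, "nuclei_seg"))
  if (!all(dim(objects_a) == dim(seg$label_image)) ||
      !all(dim(objects_b) == dim(seg$label_image)))
    stop("label images must share the segmentation shape")
  pos <- function(obj) {
    if (seg$n_cells == 0) return(logical(0))
    sel <- seg$analysis_region > 0L & obj > 0L
    if (!any(sel)) return(rep(FALSE, seg$n_cells))
    ov <- table(cell = seg$analysis_region[sel], object = obj[sel])
    hit <- rowSums(ov >= min_overlap_px) > 0
    out <- rep(FALSE, seg$n_cells)
    out[as.integer(rownames(ov))] <- hit
    out
  }
  pa <- pos(objects_a); pb <- pos(objects_b)
  calls <- data.frame(cell_id = seq_len(seg$n_cells),
                      positive_a = pa, positive_b = pb,
                      double_positive = pa & pb)
  list(calls = calls,
       counts = c(n_cells = seg$n_cells,
                  a_positive = sum(pa), b_positive = sum(pb),
                  double_positive = sum(pa & pb)))
}

#' Count double-positive cells in a two-marker slide
#'
#' Convenience wrapper: segments the DAPI channel, builds marker objects for
#' both channels and calls positivity.
#'
#' @param dapi raw DAPI channel.
#' @param marker_a,marker_b raw marker channels (channel A uses
#'   `threshold_a`, channel B `threshold_b`).
#' @param params a [positivity_params()] object.
#' @param sg a [seg_params()] object.
#' @return as [call_positivity()], plus the segmentation under `seg`.
#' @export
count_double_positive <- function(dapi, marker_a, marker_b,
                                  params = positivity_params(),
                                  sg = seg_params()) {
  seg <- segment_nuclei(dapi, sg)
  prep <- function(m) saturate_normalize(
    subtract_background(m, sg$background_sigma), sg$saturation_percentile)
  oa <- marker_objects(prep(marker_a), params$threshold_a, seg, params,
                       sg$connectivity)
  ob <- marker_objects(prep(marker_b), params$threshold_b, seg, params,
                       sg$connectivity)
  res <- call_positivity(seg, oa, ob, params$min_overlap_px)
  res$seg <- seg
  res
}
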
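# Internal helpers shared across the image modules.

# Validate a single-channel image: numeric matrix, finite, nonnegative unless
# allow_negative (background-subtracted inputs are clipped upstream, raw camera
# frames must be >= 0).
check_channel <- function(img, what = "image", allow_negative = FALSE) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(img)))
    stop(what, " contains non-finite pixels", call. = FALSE)
  if (!allow_negative && any(img < 0))
    stop(what, " contains negative pixels", call. = FALSE)
  invisible(img)
}

#' Label connected components of a binary mask
#'
#' Connected-component labelling with selectable pixel connectivity.
#' 8-connectivity (the default used throughout the pipeline) treats
#' diagonally touching pixels as one object, matching common blob-detection
#' practice.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels, 0 = background; labels are consecutive
#'   positive integers.
#' @examples
#' m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
#' max(label_components(m, 8))  # one object
#' max(label_components(m, 4))  # two objects
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (connectivity == 4 || n < 2) return(relabel_consecutive(lab))
  # bwlabel is 4-connected; merge labels that touch diagonally
  pr <- rbind(
    cbind(as.vector(lab[-1, -1]), as.vector(lab[-nrow(lab), -ncol(lab)])),
    cbind(as.vector(lab[-1, -ncol(lab)]), as.vector(lab[-nrow(lab), -1])))
  pr <- pr[pr[, 1] > 0L & pr[, 2] > 0L & pr[, 1] != pr[, 2], , drop = FALSE]
  if (nrow(pr) == 0L) return(relabel_consecutive(lab))
  pr <- unique(pr)
  parent <- seq_len(n)
  findroot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pr))) {
    a <- findroot(pr[k, 1]); b <- findroot(pr[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), findroot, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  relabel_consecutive(lab)
}

# Map positive labels to consecutive 1..k preserving first-appearance order
# (column-major scan order, deterministic).
relabel_consecutive <- function(lab) {
  pos <- lab > 0L
  if (!any(pos)) return(matrix(0L, nrow(lab), ncol(lab)))
  u <- unique(lab[pos])
  lab[pos] <- match(lab[pos], u)
  matrix(as.integer(lab), nrow(lab), ncol(lab))
}

# Areas of labels 1..max(lab).
label_areas <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = n)
}

# Drop labels listed in `drop`, relabel consecutively.
drop_labels <- function(lab, drop) {
  if (length(drop) == 0L) return(relabel_consecutive(lab))
  lab[lab %in% drop] <- 0L
  relabel_consecutive(lab)
}

# Centroids (row, col) of labels 1..n as an n x 2 matrix.
label_centroids <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  idx <- which(lab > 0L)
  l <- lab[idx]
  r <- ((idx - 1L) %% nrow(lab)) + 1L
  c <- ((idx - 1L) %/% nrow(lab)) + 1L
  cbind(rowsum(as.numeric(r), l) / tabulate(l, n),
        rowsum(as.numeric(c), l) / tabulate(l, n))
}

# Deterministic per-purpose RNG seed derived from a base seed; keeps derived
# seeds inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12289) %% 2147483647)
}
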
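#' @import methods
#' @importFrom Matrix Matrix t
NULL

# Number of clinical indicator channels per scan: CRP, ESR, lesion site,
# sex, age, and ten binary comorbidity flags, all normalized to [0, 1].
.N_INDICATORS <- 14L

#' CTScan: one CT examination
#'
#' A single scan: an ordered stack of grayscale slice images, one
#' 14-element clinical indicator vector normalized to `[0, 1]`, and a
#' binary diagnosis label.
#'
#' @slot scanId character scalar identifier.
#' @slot slices numeric array of dimension `c(h, w, n)` with values in
#'   `[0, 1]`; slice `k` is `slices[, , k]` and slices are stored in
#'   acquisition (index) order.
#' @slot indicators numeric vector of length 14, each entry in `[0, 1]`.
#' @slot label integer, 0 (negative) or 1 (positive).
#'
#' @examples
#' sc <- CTScan("s1", array(0, c(8, 8, 5)), rep(0.5, 14), 1L)
#' nSlices(sc)
#' @export
setClass("CTScan",
         representation(scanId = "character", slices = "array",
                        indicators = "numeric", label = "integer"))

setValidity("CTScan", function(object) {
  msg <- character()
  if (length(object@scanId) != 1L) msg <- c(msg, "scanId must be a scalar")
  if (length(dim(object@slices)) != 3L)
    msg <- c(msg, "slices must be an h x w x n array")
  if (length(object@indicators) != .N_INDICATORS)
    msg <- c(msg, sprintf("indicators must have length %d, got %d",
                          .N_INDICATORS, length(object@indicators)))
  if (any(!is.finite(object@indicators)) ||
      any(object@indicators < 0) || any(object@indicators > 1))
    msg <- c(msg, "indicators must lie in [0, 1]")
  if (length(object@label) != 1L || !object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' @rdname CTScan-class
#' @param scanId scan identifier.
#' @param slices slice stack array `c(h, w, n)`.
#' @param indicators numeric vector of length 14 in `[0, 1]`.
#' @param label 0 or 1.
#' @export
CTScan <- function(scanId, slices, indicators, label) {
  new("CTScan", scanId = as.character(scanId), slices = slices,
      indicators = as.numeric(indicators), label = as.integer(label))
}

#' ScanDataset: a collection of CT scans
#'
#' An ordered list of [CTScan] objects with a manifest view.
#'
#' @slot scans list of `CTScan` objects.
#' @export
setClass("ScanDataset", representation(scans = "list"))

setValidity("ScanDataset", function(object) {
  ok <- vapply(object@scans, is, TRUE, class2 = "CTScan")
  if (all(ok)) TRUE else "all elements must be CTScan objects"
})

#' @rdname ScanDataset-class
#' @param scans list of `CTScan` objects.
#' @export
ScanDataset <- function(scans) new("ScanDataset", scans = scans)

#' FeatureGraph: a weighted graph over per-slice features
#'
#' Nodes are per-slice feature vectors; each node remembers the original
#' slice index it came from, so that index-based k-nearest-neighbour
#' sparsification stays meaningful after coarsening.
#'
#' @slot features numeric matrix, one row per node.
#' @slot sliceIndices integer vector of original (0-based) slice indices,
#'   strictly increasing.
#' @slot adjacency sparse symmetric weighted adjacency (`Matrix`).
#' @export
setClass("FeatureGraph",
         representation(features = "matrix", sliceIndices = "integer",
                        adjacency = "ANY"))

setValidity("FeatureGraph", function(object) {
  msg <- character()
  n <- nrow(object@features)
  if (length(object@sliceIndices) != n)
    msg <- c(msg, "one slice index per node required")
  if (is.unsorted(object@sliceIndices, strictly = TRUE))
    msg <- c(msg, "sliceIndices must be strictly increasing")
  a <- object@adjacency
  if (!is.null(a) && (nrow(a) != n || ncol(a) != n))
    msg <- c(msg, "adjacency must be n x n")
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureGraph-class
#' @param features node feature matrix.
#' @param sliceIndices 0-based original slice index per node.
#' @param adjacency sparse adjacency matrix (may be `NULL` before
#'   sparsification).
#' @export
FeatureGraph <- function(features, sliceIndices, adjacency = NULL) {
  new("FeatureGraph", features = features,
      sliceIndices = as.integer(sliceIndices), adjacency = adjacency)
}

## ---- generics and accessors ---------------------------------------------

#' @rdname CTScan-class
#' @param object,x a `CTScan` or `ScanDataset`.
#' @export
setGeneric("scanId", function(object) standardGeneric("scanId"))
#' @rdname CTScan-class
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))
#' @rdname CTScan-class
#' @export
setGeneric("indicators", function(object) standardGeneric("indicators"))
#' @rdname CTScan-class
#' @export
setGeneric("scanLabel", function(object) standardGeneric("scanLabel"))
#' @rdname ScanDataset-class
#' @param object a `ScanDataset`.
#' @export
setGeneric("manifest", function(object) standardGeneric("manifest"))

#' @rdname CTScan-class
#' @export
setMethod("scanId", "CTScan", function(object) object@scanId)
#' @rdname CTScan-class
#' @export
setMethod("nSlices", "CTScan", function(object) dim(object@slices)[3])
#' @rdname CTScan-class
#' @export
setMethod("indicators", "CTScan", function(object) object@indicators)
#' @rdname CTScan-class
#' @export
setMethod("scanLabel", "CTScan", function(object) object@label)

#' @rdname ScanDataset-class
#' @export
setMethod("length", "ScanDataset", function(x) length(x@scans))

#' @rdname ScanDataset-class
#' @param i index.
#' @export
setMethod("[[", "ScanDataset", function(x, i) x@scans[[i]])

#' @rdname ScanDataset-class
#' @export
setMethod("manifest", "ScanDataset", function(object) {
  data.frame(
    scan_id = vapply(object@scans, scanId, ""),
    label = vapply(object@scans, scanLabel, 0L),
    n_slices = vapply(object@scans, nSlices, 0L),
    do.call(rbind, lapply(object@scans, function(s) {
      stats::setNames(as.data.frame(t(indicators(s))),
                      paste0("ind", seq_len(.N_INDICATORS)))
    })),
    stringsAsFactors = FALSE
  )
})

setMethod("show", "CTScan", function(object) {
  d <- dim(object@slices)
  cat(sprintf("CTScan '%s': %d slices of %dx%d, label=%d\n",
              object@scanId, d[3], d[1], d[2], object@label))
})

setMethod("show", "ScanDataset", function(object) {
  labs <- vapply(object@scans, scanLabel, 0L)
  cat(sprintf("ScanDataset: %d scans (%d positive, %d negative)\n",
              length(object@scans), sum(labs == 1L), sum(labs == 0L)))
})

setMethod("show", "FeatureGraph", function(object) {
  nedge <- if (is.null(object@adjacency)) 0L
           else sum(object@adjacency != 0) / 2
  cat(sprintf("FeatureGraph: %d nodes, width %d, %d undirected edges\n",
              nrow(object@features), ncol(object@features), nedge))
})

#' @rdname FeatureGraph-class
#' @param object a `FeatureGraph`.
#' @export
setGeneric("nodeFeatures", function(object) standardGeneric("nodeFeatures"))
#' @rdname FeatureGraph-class
#' @export
setGeneric("sliceIndices", function(object) standardGeneric("sliceIndices"))
#' @rdname FeatureGraph-class
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @rdname FeatureGraph-class
#' @export
setMethod("nodeFeatures", "FeatureGraph", function(object) object@features)
#' @rdname FeatureGraph-class
#' @export
setMethod("sliceIndices", "FeatureGraph", function(object) object@sliceIndices)
#' @rdname FeatureGraph-class
#' @export
setMethod("adjacency", "FeatureGraph", function(object) object@adjacency)
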
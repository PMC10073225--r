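#' Per-subject structural connectivity (streamline counts + region volumes)
#'
#' Bundles a symmetric, zero-diagonal matrix of streamline counts between
#' parcellated brain regions with the regions' volumes, the inputs from which
#' a volume-normalized weighted network is built.
#'
#' @param counts R x R symmetric nonnegative integer matrix of streamline
#'   counts; diagonal must be zero.
#' @param volumes Length-R positive numeric vector of region volumes (mm^3).
#' @param region_names Length-R unique region identifiers; defaults to the
#'   dimnames of `counts` if present.
#' @return A `fiber_connectivity` object.
#' @export
fiber_connectivity <- function(counts, volumes, region_names = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(region_names)) {
    region_names <- sprintf("roi_%03d", seq_len(nrow(counts)))
  }
  fc <- structure(
    list(counts = counts, volumes = as.numeric(volumes),
         region_names = as.character(region_names)),
    class = "fiber_connectivity"
  )
  validate_fiber_connectivity(fc)
}

validate_fiber_connectivity <- function(fc) {
  cm <- fc$counts
  r <- nrow(cm)
  if (ncol(cm) != r) abort("Fiber count matrix must be square.")
  if (length(fc$volumes) != r) abort("volumes length must match matrix size.")
  if (length(fc$region_names) != r) abort("region_names length must match matrix size.")
  if (anyDuplicated(fc$region_names)) abort("Region names must be unique.")
  if (any(fc$volumes <= 0)) abort("Region volumes must be positive.")
  if (any(cm < 0)) abort("Fiber counts must be nonnegative.")
  if (any(abs(cm - round(cm)) > 1e-8)) abort("Fiber counts must be integers.")
  if (!isTRUE(all.equal(cm, t(cm), tolerance = 0, check.attributes = FALSE))) {
    abort("Fiber count matrix must be symmetric.")
  }
  if (any(diag(cm) != 0)) abort("Fiber count matrix must have a zero diagonal.")
  dimnames(fc$counts) <- list(fc$region_names, fc$region_names)
  fc
}

#' @export
print.fiber_connectivity <- function(x, ...) {
  cat(sprintf("<fiber_connectivity> %d regions, %d nonzero connections, %s fibers total\n",
              length(x$region_names), sum(x$counts[upper.tri(x$counts)] > 0),
              format(sum(x$counts) / 2, big.mark = ",")))
  invisible(x)
}

#' Volume-normalized weighted structural network
#'
#' Connection weights are the absolute fiber count between two regions divided
#' by the volumes of the two interconnected regions. The division uses the sum
#' of the two volumes by default — the prevailing volume-correction convention
#' for streamline counts — with the product and mean conventions selectable.
#'
#' @param fibers A [fiber_connectivity()] object.
#' @param volume_convention How the two region volumes combine in the
#'   denominator: `"sum"` (default), `"product"`, or `"mean"`.
#' @return A `weighted_network` object: symmetric nonnegative weight matrix
#'   with zero diagonal, plus region names.
#' @export
build_weighted_network <- function(fibers,
                                   volume_convention = c("sum", "product", "mean")) {
  fibers <- validate_fiber_connectivity(fibers)
  volume_convention <- match.arg(volume_convention)
  v <- fibers$volumes
  denom <- switch(volume_convention,
    sum = outer(v, v, `+`),
    product = outer(v, v, `*`),
    mean = outer(v, v, `+`) / 2
  )
  w <- fibers$counts / denom
  diag(w) <- 0
  weighted_network(w, fibers$region_names)
}

#' Construct a weighted network directly from a weight matrix
#'
#' @param weights R x R symmetric nonnegative matrix with zero diagonal.
#' @param region_names Length-R unique identifiers.
#' @return A `weighted_network` object.
#' @export
weighted_network <- function(weights, region_names = rownames(weights)) {
  weights <- as.matrix(weights)
  if (is.null(region_names)) {
    region_names <- sprintf("roi_%03d", seq_len(nrow(weights)))
  }
  net <- structure(
    list(weights = weights, region_names = as.character(region_names)),
    class = "weighted_network"
  )
  validate_weighted_network(net)
}

validate_weighted_network <- function(net) {
  w <- net$weights
  r <- nrow(w)
  if (ncol(w) != r) abort("Weight matrix must be square.")
  if (length(net$region_names) != r) abort("region_names length must match matrix size.")
  if (anyDuplicated(net$region_names)) abort("Region names must be unique.")
  if (any(w < 0)) abort("Weights must be nonnegative.")
  if (!isTRUE(all.equal(w, t(w), check.attributes = FALSE))) {
    abort("Weight matrix must be symmetric.")
  }
  if (any(diag(w) != 0)) abort("Weight matrix must have a zero diagonal.")
  dimnames(net$weights) <- list(net$region_names, net$region_names)
  net
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d regions, %d edges\n",
              length(x$region_names), sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}
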
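#' Generate a synthetic cortical strip
#'
#' Builds the 1-D stand-in for the precentral gyrus: the six motor regions
#' are laid down consecutively along the dorsal -> ventral axis in
#' interdigitated order (foot, superior inter-effector, hand, middle
#' inter-effector, mouth, inferior inter-effector), with axis positions at
#' consecutive integers 0..L-1. Off-axis territories (CON, adjacent S1 and
#' background cortex) are placed on parallel rows so that every vertex has a
#' 2-D coordinate but only strip vertices lie on the seed line.
#'
#' @param verticesPerRegion integer; vertices per motor region, either a
#'   single count or a named vector over the six motor regions.
#' @param offAxis named integer vector of vertex counts for the off-strip
#'   territories (any of CON, S1_adjacent, background; 0 allowed).
#' @param hemisphere hemisphere tag, "L" or "R".
#' @return A \linkS4class{CorticalStrip}.
#' @examples
#' strip <- generateStrip(20)
#' table(regionLabels(strip))
#' @export
generateStrip <- function(verticesPerRegion = 20L,
                          offAxis = c(CON = 40L, S1_adjacent = 40L,
                                      background = 40L),
                          hemisphere = "L") {
  if (length(verticesPerRegion) == 1L && is.null(names(verticesPerRegion)))
    verticesPerRegion <- setNames(rep(as.integer(verticesPerRegion), 6L),
                                  .motorRegions)
  if (!all(.motorRegions %in% names(verticesPerRegion)))
    stop("verticesPerRegion must cover all six motor regions")
  verticesPerRegion <- verticesPerRegion[.motorRegions]
  if (any(verticesPerRegion <= 0L))
    stop("every motor region needs a positive vertex count")
  if (any(offAxis < 0L)) stop("off-axis vertex counts cannot be negative")
  if (!all(names(offAxis) %in% .offAxisRegions))
    stop("unknown off-axis region in 'offAxis'")

  L <- sum(verticesPerRegion)
  axisLabels <- rep(names(verticesPerRegion), verticesPerRegion)
  coords <- cbind(x = as.numeric(seq_len(L) - 1L), y = 0)
  labels <- axisLabels

  rowY <- c(CON = 25, S1_adjacent = 6, background = 50)
  for (reg in names(offAxis)) {
    n <- offAxis[[reg]]
    if (n == 0L) next
    coords <- rbind(coords,
                    cbind(x = seq(0, L - 1, length.out = n), y = rowY[[reg]]))
    labels <- c(labels, rep(reg, n))
  }
  rownames(coords) <- paste0("v", seq_len(nrow(coords)))
  new("CorticalStrip", coords = coords, axisLine = seq_len(L),
      regionLabels = factor(labels, levels = .allRegions[.allRegions %in%
                                                           unique(labels)]),
      hemisphere = hemisphere)
}

#' @describeIn generateStrip number of vertices.
#' @param x,object a CorticalStrip.
#' @export
setMethod("length", "CorticalStrip", function(x) nrow(x@coords))

#' Accessors for CorticalStrip
#'
#' `coords()` returns the vertex coordinate matrix, `axisLine()` the ordered
#' dorsal -> ventral vertex indices, `regionLabels()` the per-vertex region
#' factor, and `axisPositions()` the 0-based position of every vertex along
#' the axis line (nearest axis point by Euclidean distance; NA for vertices
#' farther than `maxDist` from the line).
#'
#' @param strip a \linkS4class{CorticalStrip}.
#' @return See individual descriptions.
#' @export
coords <- function(strip) strip@coords

#' @rdname coords
#' @export
axisLine <- function(strip) strip@axisLine

#' @rdname coords
#' @export
regionLabels <- function(strip) strip@regionLabels

#' @rdname coords
#' @param maxDist off-axis vertices farther than this from the line get NA.
#' @export
axisPositions <- function(strip, maxDist = Inf) {
  ax <- strip@coords[strip@axisLine, , drop = FALSE]
  pos <- projectToAxis(strip@coords, ax)
  if (is.finite(maxDist)) {
    d <- sqrt(rowSums((strip@coords - ax[pos + 1L, , drop = FALSE])^2))
    pos[d > maxDist] <- NA_integer_
  }
  pos
}

#' @describeIn generateStrip vertex indices belonging to a set of regions.
#' @param regions character vector of region labels.
#' @export
regionVertices <- function(strip, regions) {
  idx <- which(as.character(strip@regionLabels) %in% regions)
  if (!length(idx))
    stop("no vertices labelled ", paste(regions, collapse = "/"))
  idx
}

setMethod("show", "CorticalStrip", function(object) {
  cat("CorticalStrip (", object@hemisphere, "): ", length(object),
      " vertices, axis length ", length(object@axisLine), "\n", sep = "")
  print(table(object@regionLabels))
})
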
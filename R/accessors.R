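# Accessor generics and show methods for the core classes.

#' @describeIn GradientScheme b-values, one per measurement.
#' @param object a \code{GradientScheme}.
#' @export
setGeneric("bvalues", function(object) standardGeneric("bvalues"))

#' @rdname GradientScheme-class
#' @export
setMethod("bvalues", "GradientScheme", function(object) object@bval)

#' @describeIn GradientScheme unit gradient directions (n x 3).
#' @export
setGeneric("directions", function(object) standardGeneric("directions"))

#' @rdname GradientScheme-class
#' @export
setMethod("directions", "GradientScheme", function(object) object@dirs)

#' @describeIn GradientScheme number of diffusion-weighted shells.
#' @export
setGeneric("nShells", function(object) standardGeneric("nShells"))

#' @rdname GradientScheme-class
#' @export
setMethod("nShells", "GradientScheme", function(object)
  length(object@shellB))

#' @describeIn GradientScheme shell summary: b-value, direction count and
#'   minimum pairwise angle (degrees) per shell, plus the b=0 count.
#' @export
setGeneric("shellTable", function(object) standardGeneric("shellTable"))

#' @rdname GradientScheme-class
#' @export
setMethod("shellTable", "GradientScheme", function(object) {
  k <- length(object@shellB)
  data.frame(
    b = object@shellB,
    n = lengths(object@shellIndex),
    minAngleDeg = vapply(object@shellIndex, function(ix) {
      if (length(ix) < 2L) return(NA_real_)
      minAngle(object@dirs[ix, , drop = FALSE]) * 180 / pi
    }, numeric(1))
  )
})

setMethod("show", "GradientScheme", function(object) {
  cat(sprintf("GradientScheme: %d measurements, %d shells, %d b=0 volumes\n",
              length(object@bval), length(object@shellB),
              length(object@b0Index)))
  if (length(object@shellB)) {
    tab <- shellTable(object)
    for (i in seq_len(nrow(tab)))
      cat(sprintf("  b = %6.0f s/mm^2: %3d directions (min angle %.1f deg)\n",
                  tab$b[i], tab$n[i], tab$minAngleDeg[i]))
  }
})

setMethod("show", "StandardModelKernel", function(object) {
  cat(sprintf(
    "StandardModelKernel: f = %.3f, Di = %.3f, De = %.3f, Dr = %.3f um^2/ms\n",
    object@f, object@Di, object@De, object@Dr))
})
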
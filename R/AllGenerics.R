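#' Accessors for quantalglu classes
#'
#' Small accessor generics so downstream code never touches slots
#' directly: \code{nDocked} (number of release-ready vesicles),
#' \code{pVes} (per-vesicle release probability, optionally for one
#' condition), \code{quantalSize} (q), \code{bMax}, \code{conditionNames},
#' \code{amplitudes} (the per-trial table), \code{sigma0},
#' \code{baselineFwhm}, \code{pSyn}, \code{trueCounts},
#' \code{trialMatrices} and \code{noiseModel}.
#'
#' @param object an object of the documented classes.
#' @param condition optional condition label.
#' @param ... unused.
#' @return The corresponding component, see the method signatures.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nDocked", function(object) standardGeneric("nDocked"))
#' @rdname accessors
#' @export
setGeneric("pVes", function(object, condition = NULL) standardGeneric("pVes"))
#' @rdname accessors
#' @export
setGeneric("quantalSize", function(object) standardGeneric("quantalSize"))
#' @rdname accessors
#' @export
setGeneric("bMax", function(object) standardGeneric("bMax"))
#' @rdname accessors
#' @export
setGeneric("kD", function(object) standardGeneric("kD"))
#' @rdname accessors
#' @export
setGeneric("conditionNames", function(object) standardGeneric("conditionNames"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object, ...) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("sigma0", function(object, condition = NULL)
  standardGeneric("sigma0"))
#' @rdname accessors
#' @export
setGeneric("baselineFwhm", function(object) standardGeneric("baselineFwhm"))
#' @rdname accessors
#' @export
setGeneric("pSyn", function(object, condition = NULL) standardGeneric("pSyn"))
#' @rdname accessors
#' @export
setGeneric("trueCounts", function(object, condition = NULL)
  standardGeneric("trueCounts"))
#' @rdname accessors
#' @export
setGeneric("trialMatrices", function(object, condition = NULL)
  standardGeneric("trialMatrices"))
#' @rdname accessors
#' @export
setGeneric("noiseModel", function(object, condition = NULL)
  standardGeneric("noiseModel"))

#' Synaptic strength of a fitted bouton
#'
#' Synaptic strength is the product of quantal parameters
#' \eqn{p_{ves} \times N \times q} (in \eqn{\Delta F/F_0}-equivalents);
#' unlike the mean measured response it is free of the compressive effect
#' of indicator saturation.
#'
#' @param object a \linkS4class{QuantalFit} (or \linkS4class{GroundTruth}
#'   for the generating values).
#' @param condition condition label; when NULL, all conditions.
#' @return Named numeric vector of strengths.
#' @examples
#' synapticStrength(gluGroundTruth())      # 3 * c(0.08, 0.79) * 0.84
#' @export
setGeneric("synapticStrength", function(object, condition = NULL)
  standardGeneric("synapticStrength"))

## ---- methods -------------------------------------------------------------

.pickCondition <- function(x, condition) {
  if (is.null(condition)) return(x)
  if (!all(condition %in% names(x)))
    stop("unknown condition label: ",
         paste(setdiff(condition, names(x)), collapse = ", "), call. = FALSE)
  x[condition]
}

#' @rdname accessors
#' @export
setMethod("nDocked", "GroundTruth", function(object) object@nDocked)
#' @rdname accessors
#' @export
setMethod("nDocked", "QuantalFit", function(object) object@nDocked)
#' @rdname accessors
#' @export
setMethod("pVes", "GroundTruth", function(object, condition = NULL)
  .pickCondition(object@pVes, condition))
#' @rdname accessors
#' @export
setMethod("pVes", "QuantalFit", function(object, condition = NULL)
  .pickCondition(object@pVes, condition))
#' @rdname accessors
#' @export
setMethod("quantalSize", "GroundTruth", function(object) object@q)
#' @rdname accessors
#' @export
setMethod("quantalSize", "QuantalFit", function(object) object@q)
#' @rdname accessors
#' @export
setMethod("bMax", "GroundTruth", function(object) object@bMax)
#' @rdname accessors
#' @export
setMethod("bMax", "QuantalFit", function(object) object@bMax)
#' @rdname accessors
#' @export
setMethod("bMax", "SaturationCurve", function(object) object@bMax)
#' @rdname accessors
#' @export
setMethod("kD", "SaturationCurve", function(object) object@kD)
#' @rdname accessors
#' @export
setMethod("conditionNames", "GroundTruth", function(object)
  names(object@pVes))
#' @rdname accessors
#' @export
setMethod("conditionNames", "GluSession", function(object)
  object@conditions)
#' @rdname accessors
#' @export
setMethod("conditionNames", "AmplitudeSet", function(object)
  names(object@psyn))
#' @rdname accessors
#' @export
setMethod("amplitudes", "AmplitudeSet", function(object, ...) object@table)
#' @rdname accessors
#' @export
setMethod("sigma0", "NoiseModel", function(object, condition = NULL)
  object@sigma0)
#' @rdname accessors
#' @export
setMethod("sigma0", "AmplitudeSet", function(object, condition = NULL) {
  out <- vapply(object@noise, function(nm) nm@sigma0, 1.0)
  .pickCondition(out, condition)
})
#' @rdname accessors
#' @export
setMethod("baselineFwhm", "NoiseModel", function(object) object@fwhm)
#' @rdname accessors
#' @export
setMethod("pSyn", "AmplitudeSet", function(object, condition = NULL)
  .pickCondition(object@psyn, condition))
#' @rdname accessors
#' @export
setMethod("trueCounts", "GluSession", function(object, condition = NULL) {
  led <- object@ledger
  if (!is.null(condition)) {
    if (!all(condition %in% object@conditions))
      stop("unknown condition label", call. = FALSE)
    led <- led[led$condition %in% condition, ]
  }
  led$k
})
#' @rdname accessors
#' @export
setMethod("trialMatrices", "GluSession", function(object, condition = NULL) {
  if (is.null(condition)) return(object@trials)
  if (!all(condition %in% object@conditions))
    stop("unknown condition label", call. = FALSE)
  if (length(condition) == 1L) object@trials[[condition]]
  else object@trials[condition]
})
#' @rdname accessors
#' @export
setMethod("noiseModel", "AmplitudeSet", function(object, condition = NULL) {
  if (is.null(condition)) return(object@noise)
  if (!all(condition %in% names(object@noise)))
    stop("unknown condition label", call. = FALSE)
  if (length(condition) == 1L) object@noise[[condition]]
  else object@noise[condition]
})

#' @rdname synapticStrength
#' @export
setMethod("synapticStrength", "QuantalFit", function(object,
                                                     condition = NULL)
  .pickCondition(object@strength, condition))
#' @rdname synapticStrength
#' @export
setMethod("synapticStrength", "GroundTruth", function(object,
                                                      condition = NULL)
  .pickCondition(object@pVes * object@nDocked * object@q, condition))
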
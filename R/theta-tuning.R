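#' Squared weight disagreement with a reference network
#'
#' Integrates the component networks at a given `theta`, restricts to the
#' edges present in both the integrated network and the reference, and returns
#' the sum of squared weight differences over those shared edges. This is the
#' objective minimized when selecting the adjustment exponent against an
#' independent functional reference (a GO-style network).
#'
#' @param theta positive adjustment exponent.
#' @param nets list of component [WeightedNetwork-class] objects, or a
#'   prebuilt [UnionProfile-class].
#' @param reference a [WeightedNetwork-class] with weights in `(0, 1]`
#'   sharing at least one edge with the union of `nets`.
#' @param config an [IntegrationConfig-class] supplying `epsilon`.
#' @return a non-negative number (squared-weight units).
#' @seealso [tuneTheta()]
#' @export
tuningObjective <- function(theta, nets, reference,
                            config = integrationConfig()) {
    .assertScalarNumeric(theta, "theta")
    stopifnot(is(reference, "WeightedNetwork"), is(config, "IntegrationConfig"))
    profile <- if (is(nets, "UnionProfile")) nets
               else buildUnion(nets, config@epsilon)
    w <- .integrateProfile(profile, theta)
    key <- .edgeKey(profile@edges$from, profile@edges$to)
    refKey <- .edgeKey(reference@edges$from, reference@edges$to)
    idx <- match(refKey, key)
    shared <- which(!is.na(idx))
    if (length(shared) == 0)
        stop("no edges shared with the reference network; objective undefined",
             call. = FALSE)
    sum((w[idx[shared]] - reference@edges$weight[shared])^2)
}

#' Select the adjustment exponent by grid search
#'
#' Evaluates [tuningObjective()] on the inclusive theta grid of `config`
#' (default 0.2 to 0.6 in steps of 0.01) and returns the full curve with the
#' minimizing theta. The objective is cheap and possibly non-convex, so an
#' exhaustive sweep is used; ties are broken toward the smallest theta for
#' determinism.
#'
#' @inheritParams tuningObjective
#' @return a [ThetaFit-class].
#' @examples
#' \dontrun{
#' fit <- tuneTheta(nets, reference)
#' bestTheta(fit)
#' }
#' @export
tuneTheta <- function(nets, reference, config = integrationConfig()) {
    stopifnot(is(config, "IntegrationConfig"))
    grid <- config@thetaGrid
    if (length(grid) == 1)
        warning("degenerate single-point grid; returning that point")
    profile <- if (is(nets, "UnionProfile")) nets
               else buildUnion(nets, config@epsilon)
    obj <- vapply(grid, tuningObjective, 0, nets = profile,
                  reference = reference, config = config)
    key <- .edgeKey(profile@edges$from, profile@edges$to)
    refKey <- .edgeKey(reference@edges$from, reference@edges$to)
    nShared <- sum(refKey %in% key)
    new("ThetaFit", grid = grid, objective = obj,
        bestTheta = grid[which.min(obj)], nSharedEdges = as.integer(nShared))
}

#' @rdname accessors
#' @export
setMethod("bestTheta", "ThetaFit", function(x) x@bestTheta)

#' Tuning curve as a data frame
#'
#' @param x a [ThetaFit-class].
#' @return `data.frame` with columns `theta` and `objective`.
#' @export
tuningCurve <- function(x) {
    stopifnot(is(x, "ThetaFit"))
    data.frame(theta = x@grid, objective = x@objective)
}

setMethod("show", "ThetaFit", function(object) {
    cat(sprintf("ThetaFit over [%g, %g] (%d points, %d shared edges)\n",
                min(object@grid), max(object@grid), length(object@grid),
                object@nSharedEdges))
    cat(sprintf("  best theta = %g (objective = %g)\n", object@bestTheta,
                min(object@objective)))
})
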
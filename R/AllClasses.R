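#' RegulonSet: a collection of activating regulons
#'
#' A regulon is a transcription factor together with the target genes it is
#' inferred to activate, each target carrying a positive importance weight.
#' Regulons are named `"<TF>(+)"` following the SCENIC convention for
#' activating arcs.
#'
#' @slot elements Named list; each element is a list with fields `tf`
#'   (character scalar), `targets` (character vector) and `importance`
#'   (numeric vector named by target).
#'
#' @seealso [assembleRegulons()], [regulonsToGeneSets()], [rasMatrix()]
#' @export
setClass("RegulonSet", representation(elements = "list"))

setValidity("RegulonSet", function(object) {
    el <- object@elements
    msgs <- character()
    if (length(el)) {
        if (is.null(names(el)) || anyDuplicated(names(el)))
            msgs <- c(msgs, "regulon names must be unique and non-NULL")
        for (nm in names(el)) {
            r <- el[[nm]]
            if (!all(c("tf", "targets", "importance") %in% names(r))) {
                msgs <- c(msgs, sprintf("regulon '%s' lacks tf/targets/importance", nm))
                next
            }
            if (r$tf %in% r$targets)
                msgs <- c(msgs, sprintf("regulon '%s': TF appears in its own targets", nm))
            if (anyDuplicated(r$targets))
                msgs <- c(msgs, sprintf("regulon '%s': duplicated targets", nm))
            if (length(r$importance) != length(r$targets) || any(r$importance <= 0))
                msgs <- c(msgs, sprintf("regulon '%s': importances must be positive, one per target", nm))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a RegulonSet
#'
#' @param tfs Character vector of transcription-factor gene ids.
#' @param targets List of character vectors, one per TF, of target gene ids.
#' @param importance List of positive numeric vectors parallel to `targets`.
#' @return A [RegulonSet-class] whose regulons are named `"<TF>(+)"`.
#' @examples
#' rs <- RegulonSet("TF1", list(c("g1", "g2")), list(c(0.9, 0.4)))
#' regulonNames(rs)
#' @export
RegulonSet <- function(tfs, targets, importance) {
    stopifnot(length(tfs) == length(targets), length(tfs) == length(importance))
    el <- vector("list", length(tfs))
    for (i in seq_along(tfs)) {
        imp <- as.numeric(importance[[i]])
        names(imp) <- targets[[i]]
        el[[i]] <- list(tf = tfs[i], targets = as.character(targets[[i]]),
                        importance = imp)
    }
    names(el) <- paste0(tfs, "(+)")
    new("RegulonSet", elements = el)
}

#' @describeIn RegulonSet-class Number of regulons.
#' @param x A `RegulonSet`.
#' @export
setMethod("length", "RegulonSet", function(x) length(x@elements))

#' @describeIn RegulonSet-class Regulon names (`"TF(+)"`).
#' @export
setMethod("names", "RegulonSet", function(x) names(x@elements))

#' Regulon accessors
#'
#' @param x A [RegulonSet-class].
#' @return `regulonNames()` the `"TF(+)"` names; `regulonTF()` the TF gene id
#'   per regulon; `regulonTargets()` a named list of target-gene vectors;
#'   `regulonSizes()` the number of targets per regulon.
#' @export
regulonNames <- function(x) names(x@elements)

#' @rdname regulonNames
#' @export
regulonTF <- function(x) vapply(x@elements, `[[`, character(1), "tf")

#' @rdname regulonNames
#' @export
regulonTargets <- function(x) lapply(x@elements, `[[`, "targets")

#' @rdname regulonNames
#' @export
regulonSizes <- function(x) vapply(x@elements, function(r) length(r$targets), integer(1))

#' @describeIn RegulonSet-class Extract one regulon (a list with `tf`,
#'   `targets`, `importance`).
#' @param i Index or regulon name.
#' @export
setMethod("[[", "RegulonSet", function(x, i) x@elements[[i]])

#' @describeIn RegulonSet-class Subset to several regulons.
#' @export
setMethod("[", "RegulonSet", function(x, i) new("RegulonSet", elements = x@elements[i]))

setMethod("show", "RegulonSet", function(object) {
    n <- length(object)
    cat(sprintf("RegulonSet with %d regulon%s\n", n, if (n == 1) "" else "s"))
    if (n) {
        sz <- regulonSizes(object)
        cat(sprintf("  sizes: min %d / median %s / max %d targets\n",
                    min(sz), format(median(sz)), max(sz)))
        cat("  names:", paste(head(names(object), 5), collapse = ", "),
            if (n > 5) "..." else "", "\n")
    }
})
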
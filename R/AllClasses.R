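#' @import methods
#' @importFrom stats cor dist lm median p.adjust pnorm prcomp predict
#'   quantile rbeta rbinom rlnorm rnbinom rnorm runif sd setNames var
#'   wilcox.test glm coef poisson vcov
#' @importFrom utils read.delim write.table head
NULL

#' Reference atlas of cell-type centroid expression
#'
#' Holds mean log-expression centroids for a set of reference cell types
#' over a common gene universe, together with an optional super-type
#' grouping (for peripheral neurons, typically the source ganglion:
#' sympathetic CG-derived versus sensory DRG-derived types). Query cells
#' are annotated by correlating their profiles against these centroids.
#'
#' @slot profiles numeric matrix, genes x cell types; mean log-normalized
#'   expression per type. Row names are gene ids, column names type labels.
#' @slot superType named character vector mapping each type label to a
#'   super-type group (e.g. `"CG"`, `"DRG"`).
#' @slot note free-text provenance of the atlas.
#'
#' @seealso [labelTransfer()], [generateReferenceAtlas()]
#' @export
setClass("ReferenceAtlas",
  representation(
    profiles  = "matrix",
    superType = "character",
    note      = "character"
  )
)

setValidity("ReferenceAtlas", function(object) {
  p <- object@profiles
  msg <- character()
  if (is.null(rownames(p)) || is.null(colnames(p)))
    msg <- c(msg, "profiles must have gene row names and type column names")
  if (!is.null(colnames(p)) && anyDuplicated(colnames(p)))
    msg <- c(msg, "duplicate cell-type labels")
  if (nrow(p) == 0L)
    msg <- c(msg, "gene universe is empty")
  if (!all(is.finite(p)))
    msg <- c(msg, "centroids must be finite")
  if (length(object@superType) &&
      !all(colnames(p) %in% names(object@superType)))
    msg <- c(msg, "superType must cover every type label")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceAtlas
#'
#' @param profiles genes x types matrix of centroid log-expression with
#'   dimnames.
#' @param superType named character vector mapping type labels to
#'   super-types; defaults to each type being its own super-type.
#' @param note provenance string.
#' @return A [ReferenceAtlas-class] object.
#' @export
ReferenceAtlas <- function(profiles, superType = NULL, note = "") {
  if (is.null(superType))
    superType <- setNames(colnames(profiles), colnames(profiles))
  new("ReferenceAtlas", profiles = as.matrix(profiles),
      superType = superType, note = note)
}

#' @describeIn ReferenceAtlas centroid matrix (genes x types)
#' @param atlas,object a `ReferenceAtlas`
#' @export
atlasProfiles <- function(atlas) atlas@profiles

#' @describeIn ReferenceAtlas cell-type labels
#' @export
atlasTypes <- function(atlas) colnames(atlas@profiles)

#' @describeIn ReferenceAtlas super-type of each type label
#' @export
atlasSuperTypes <- function(atlas) atlas@superType[atlasTypes(atlas)]

setMethod("show", "ReferenceAtlas", function(object) {
  cat("ReferenceAtlas with", ncol(object@profiles), "cell types over",
      nrow(object@profiles), "genes\n")
  cat("types:", paste(atlasTypes(object), collapse = ", "), "\n")
  if (nzchar(object@note)) cat("note:", object@note, "\n")
})

#' Consensus up/down gene signature
#'
#' Two disjoint gene sets (`up`, `down`) built from per-subpopulation
#' differential-expression results, with per-gene provenance recording the
#' contributing subpopulations and direction, plus the parameters used.
#' Genes selected in both directions are dropped from both sets and listed
#' in `conflicts`.
#'
#' @slot name signature name.
#' @slot up,down character vectors of gene ids.
#' @slot provenance data.frame with columns `gene`, `direction`,
#'   `populations` (comma-separated contributing subpopulations).
#' @slot conflicts genes removed because selected in both directions.
#' @slot params list of the [signatureParams()] used.
#' @export
setClass("PCNSignature",
  representation(
    name       = "character",
    up         = "character",
    down       = "character",
    provenance = "data.frame",
    conflicts  = "character",
    params     = "list"
  )
)

setValidity("PCNSignature", function(object) {
  msg <- character()
  if (length(intersect(object@up, object@down)))
    msg <- c(msg, "up and down sets must be disjoint")
  if (anyDuplicated(object@up) || anyDuplicated(object@down))
    msg <- c(msg, "duplicate genes within a set")
  if (length(msg)) msg else TRUE
})

#' @describeIn PCNSignature up-regulated gene set
#' @param x a `PCNSignature`
#' @export
signatureUp <- function(x) x@up

#' @describeIn PCNSignature down-regulated gene set
#' @export
signatureDown <- function(x) x@down

#' @describeIn PCNSignature per-gene provenance table
#' @export
signatureProvenance <- function(x) x@provenance

setMethod("show", "PCNSignature", function(object) {
  cat("PCNSignature '", object@name, "': ", length(object@up), " up, ",
      length(object@down), " down", sep = "")
  if (length(object@conflicts))
    cat(" (", length(object@conflicts), " direction conflicts dropped)",
        sep = "")
  cat("\n")
})
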
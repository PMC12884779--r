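#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData rowData
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Single-cell reference experiment
#'
#' A \linkS4class{SingleCellExperiment} whose \code{counts} assay holds a
#' non-negative gene-by-cell count matrix and whose \code{colData} carries at
#' least a \code{cell_type} column. Optional columns \code{batch},
#' \code{tissue} and \code{patient} annotate confounders and sample origin.
#'
#' @slot int_elementMetadata,int_colData,int_metadata inherited internals.
#' @seealso [ScReference()] for the validated constructor.
#' @export
setClass("ScReference", contains = "SingleCellExperiment")

setValidity("ScReference", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (min(cts) < 0) msg <- c(msg, "counts must be non-negative")
    }
    if (!"cell_type" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'cell_type' is required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers (rownames) must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "cell identifiers (colnames) must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a validated single-cell reference
#'
#' @param counts non-negative numeric or sparse matrix, genes in rows and
#'   cells in columns; dimnames are taken as gene and cell identifiers.
#' @param cell_type character/factor of length \code{ncol(counts)}.
#' @param batch,tissue,patient optional per-cell annotations.
#' @return An [ScReference-class] object.
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' sc <- ScReference(m, cell_type = c("A", "A", "B", "B"))
#' @export
ScReference <- function(counts, cell_type, batch = NULL, tissue = NULL,
                        patient = NULL) {
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' must carry gene rownames and cell colnames")
    n <- ncol(counts)
    cd <- DataFrame(cell_type = as.character(cell_type), row.names = colnames(counts))
    for (nm in c("batch", "tissue", "patient")) {
        v <- get(nm)
        if (!is.null(v)) {
            if (length(v) != n)
                stop("annotation '", nm, "' must have one entry per cell")
            cd[[nm]] <- as.character(v)
        }
    }
    if (length(cell_type) != n)
        stop("'cell_type' must have one entry per cell")
    new("ScReference",
        SingleCellExperiment(assays = list(counts = counts), colData = cd))
}

#' Bulk expression experiment
#'
#' A \linkS4class{SummarizedExperiment} holding a non-negative gene-by-sample
#' expression matrix in assay \code{values} (counts or normalised units).
#'
#' @seealso [BulkExpression()]
#' @export
setClass("BulkExpression", contains = "SummarizedExperiment")

setValidity("BulkExpression", function(object) {
    msg <- character()
    if (!"values" %in% assayNames(object))
        msg <- c(msg, "assay 'values' is required")
    else if (min(assay(object, "values")) < 0)
        msg <- c(msg, "expression values must be non-negative")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    if (length(msg)) msg else TRUE
})

#' @param values non-negative matrix, genes in rows, samples in columns.
#' @return A [BulkExpression-class] object.
#' @rdname BulkExpression-class
#' @export
BulkExpression <- function(values) {
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must carry gene rownames and sample colnames")
    new("BulkExpression",
        SummarizedExperiment(assays = list(values = as.matrix(values))))
}

#' Latent embedding of cells or bulk samples
#'
#' Rows are cells or bulk samples, columns are latent coordinates produced by
#' a trained encoder. Reference and bulk embeddings from the same model share
#' the latent dimension.
#'
#' @slot coordinates numeric matrix (rows x latent dims) with row names.
#' @export
setClass("LatentEmbedding", representation(coordinates = "matrix"))

setValidity("LatentEmbedding", function(object) {
    if (is.null(rownames(object@coordinates)))
        return("coordinates must carry row identifiers")
    if (anyDuplicated(rownames(object@coordinates)))
        return("row identifiers must be unique")
    TRUE
})

#' @param coordinates numeric matrix with row names.
#' @rdname LatentEmbedding-class
#' @export
LatentEmbedding <- function(coordinates)
    new("LatentEmbedding", coordinates = as.matrix(coordinates))

#' @describeIn LatentEmbedding-class extract the coordinate matrix.
#' @param object a \code{LatentEmbedding}.
#' @export
latentCoords <- function(object) object@coordinates

#' Per-cell-type reference panel of median latent vectors
#'
#' Each row is the coordinate-wise median of one cell type's latent vectors;
#' this is the matrix \eqn{R} that bulk embeddings are regressed against.
#'
#' @slot panel numeric matrix (cell types x latent dims), rownames = types.
#' @export
setClass("ReferencePanel", representation(panel = "matrix"))

setValidity("ReferencePanel", function(object) {
    if (is.null(rownames(object@panel))) return("panel rows must be named by cell type")
    if (anyDuplicated(rownames(object@panel))) return("cell types must be unique")
    TRUE
})

#' @param panel numeric matrix with cell-type rownames.
#' @rdname ReferencePanel-class
#' @export
ReferencePanel <- function(panel) new("ReferencePanel", panel = as.matrix(panel))

#' @describeIn ReferencePanel-class the cell-type-by-latent matrix.
#' @param object a \code{ReferencePanel}.
#' @export
panelMatrix <- function(object) object@panel

#' @describeIn ReferencePanel-class ordered cell-type labels.
#' @export
cellTypes <- function(object) rownames(object@panel)

#' Estimated cell-type proportions
#'
#' Per-sample probability vectors over the reference cell types, together
#' with the raw (pre-clip) regression coefficients and a flag for samples
#' whose coefficients were all non-positive (uniform fallback).
#'
#' @slot proportions samples x cell types; rows sum to 1, entries >= 0.
#' @slot rawCoefficients samples x cell types, before clipping.
#' @slot degenerate logical per sample.
#' @slot method character, estimator used.
#' @export
setClass("ProportionEstimate",
         representation(proportions = "matrix", rawCoefficients = "matrix",
                        degenerate = "logical", method = "character"))

setValidity("ProportionEstimate", function(object) {
    P <- object@proportions
    msg <- character()
    if (min(P) < 0) msg <- c(msg, "proportions must be non-negative")
    if (any(abs(rowSums(P) - 1) > 1e-9))
        msg <- c(msg, "each proportion vector must sum to 1 (tol 1e-9)")
    if (length(object@degenerate) != nrow(P))
        msg <- c(msg, "one degenerate flag per sample required")
    if (length(msg)) msg else TRUE
})

#' @describeIn ProportionEstimate-class the samples x cell-types matrix.
#' @param object a \code{ProportionEstimate}.
#' @export
proportions <- function(object) object@proportions

#' @describeIn ProportionEstimate-class raw pre-clip coefficients.
#' @export
rawCoefficients <- function(object) object@rawCoefficients

#' @describeIn ProportionEstimate-class uniform-fallback flags.
#' @export
degenerateFlags <- function(object) object@degenerate

#' Trained adversarial deconfounding autoencoder
#'
#' Holds encoder/decoder/adversary parameters, the ordered gene panel the
#' encoder expects, and per-epoch training history. The encoder is a
#' deterministic function at inference time: cells and bulk samples are
#' embedded by the very same map.
#'
#' @slot encoder,decoder lists of layer weight/bias matrices.
#' @slot adversaries list of adversary networks, one per confounder.
#' @slot panelGenes ordered gene identifiers the model was trained on.
#' @slot latentDim integer latent dimensionality.
#' @slot confounderLevels list of class-label vectors per confounder.
#' @slot history data.frame of per-epoch losses.
#' @slot config list of training settings.
#' @export
setClass("AAEModel",
         representation(encoder = "list", decoder = "list",
                        adversaries = "list", panelGenes = "character",
                        latentDim = "integer", confounderLevels = "list",
                        history = "data.frame", config = "list"))

#' @describeIn AAEModel-class gene panel the encoder expects, in order.
#' @param object an \code{AAEModel}.
#' @export
panelGenes <- function(object) object@panelGenes

#' @describeIn AAEModel-class training history (one row per epoch/phase).
#' @export
trainingHistory <- function(object) object@history

setMethod("show", "ScReference", function(object) {
    cat("ScReference:", nrow(object), "genes x", ncol(object), "cells\n")
    cat("  cell types:", paste(sort(unique(object$cell_type)), collapse = ", "), "\n")
    if ("batch" %in% colnames(colData(object)))
        cat("  batches:   ", paste(sort(unique(object$batch)), collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "LatentEmbedding", function(object) {
    d <- dim(object@coordinates)
    cat("LatentEmbedding:", d[1], "rows x", d[2], "latent dims\n")
    invisible(NULL)
})

setMethod("show", "ReferencePanel", function(object) {
    cat("ReferencePanel:", nrow(object@panel), "cell types x",
        ncol(object@panel), "latent dims\n")
    cat("  types:", paste(rownames(object@panel), collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "ProportionEstimate", function(object) {
    cat("ProportionEstimate:", nrow(object@proportions), "samples x",
        ncol(object@proportions), "cell types (method:", object@method, ")\n")
    if (any(object@degenerate))
        cat("  degenerate samples:", sum(object@degenerate), "\n")
    invisible(NULL)
})

setMethod("show", "AAEModel", function(object) {
    cat("AAEModel:", length(object@panelGenes), "panel genes ->",
        object@latentDim, "latent dims;",
        length(object@adversaries), "adversary(ies)\n")
    if (nrow(object@history))
        cat("  trained phases:", paste(unique(object@history$phase), collapse = " -> "), "\n")
    invisible(NULL)
})
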
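#' Draw random cell-type proportions for a pseudobulk sample
#'
#' One uniform(0,1) draw per cell type, normalised to sum to one:
#' \eqn{f_c = r_c / \sum_{C_{all}} r_c}.
#'
#' @param cellTypes character vector of cell-type labels (>= 2).
#' @param seed integer seed.
#' @return list with \code{r} (raw draws) and \code{f} (proportions), both
#'   named by cell type.
#' @export
drawRandomProportions <- function(cellTypes, seed = 1) {
    if (length(cellTypes) < 2) stop("at least two cell types required")
    set.seed(seed)
    r <- stats::runif(length(cellTypes))
    names(r) <- cellTypes
    list(r = r, f = r / sum(r))
}

#' Apportion cells to types by largest remainder
#'
#' Converts continuous proportions \eqn{f_c} and a total \eqn{N_{total}}
#' into integer per-type cell counts \eqn{N_c} that sum exactly to
#' \eqn{N_{total}} (largest-remainder rounding of \eqn{f_c N_{total}}; ties
#' broken in type order).
#'
#' @param f named non-negative proportions.
#' @param nTotal total number of cells.
#' @return named integer vector of counts.
#' @export
apportionCells <- function(f, nTotal) {
    if (nTotal < length(f)) stop("nTotal must be at least the number of types")
    n <- largestRemainder(f, nTotal)
    names(n) <- names(f)
    n
}

#' Simulate pseudobulks with random proportions
#'
#' For each sample: draw proportions uniformly (one draw per cell type,
#' normalised), apportion \code{nCellsPerSample} cells over the types, sample
#' that many cells of each type from the reference (without replacement when
#' enough cells exist, with replacement otherwise — recorded in provenance)
#' and sum their raw counts. Ground-truth proportions are the realized cell
#' fractions \eqn{N_c / N_{total}}.
#'
#' @param sc an [ScReference-class]; every cell type must have >= 1 cell.
#' @param nSamples number of pseudobulks (the reference design uses 100).
#' @param nCellsPerSample cells mixed into each pseudobulk; defaults to the
#'   number of cells in \code{sc}.
#' @param seed integer master seed.
#' @return list with \code{expression} (genes x samples matrix of summed
#'   counts), \code{trueProportions} (samples x cell types),
#'   \code{provenance} (per-sample list: selected cell ids, replacement
#'   flag).
#' @export
simulateBulkRandom <- function(sc, nSamples = 100, nCellsPerSample = NULL,
                               seed = 1) {
    cts <- as.matrix(assay(sc, "counts"))
    types <- sort(unique(sc$cell_type))
    byType <- split(seq_len(ncol(cts)), sc$cell_type)[types]
    if (any(vapply(byType, length, integer(1)) == 0))
        stop("every cell type needs at least one cell")
    if (is.null(nCellsPerSample)) nCellsPerSample <- ncol(cts)
    expr <- matrix(0, nrow(cts), nSamples,
                   dimnames = list(rownames(cts), sprintf("bulk%03d", seq_len(nSamples))))
    P <- matrix(0, nSamples, length(types),
                dimnames = list(colnames(expr), types))
    prov <- vector("list", nSamples)
    for (s in seq_len(nSamples)) {
        f <- if (length(types) == 1) stats::setNames(1, types)
             else drawRandomProportions(types, seed = seed + s - 1)$f
        N <- apportionCells(f, nCellsPerSample)
        set.seed(seed * 1000L + s)
        sel <- integer(0); repl <- FALSE
        for (tp in types) {
            pool <- byType[[tp]]
            if (N[tp] == 0) next
            if (N[tp] <= length(pool)) {
                sel <- c(sel, sample(pool, N[tp]))
            } else {
                sel <- c(sel, sample(pool, N[tp], replace = TRUE))
                repl <- TRUE
            }
        }
        expr[, s] <- rowSums(cts[, sel, drop = FALSE])
        P[s, ] <- N / sum(N)
        prov[[s]] <- list(cells = colnames(cts)[sel], with_replacement = repl)
    }
    list(expression = expr, trueProportions = P, provenance = prov,
         strategy = "random_proportion")
}

#' Simulate pseudobulks patient-wise
#'
#' One pseudobulk per patient: the exact per-gene sum of all that patient's
#' cell count vectors. Ground-truth proportions are the patient's cell-type
#' count fractions. Patients with zero cells are skipped with a warning.
#'
#' @param sc an [ScReference-class] with a \code{patient} annotation.
#' @return list with \code{expression} (genes x patients),
#'   \code{trueProportions} (patients x cell types) and \code{provenance}.
#' @export
simulateBulkPatientwise <- function(sc) {
    if (!"patient" %in% colnames(colData(sc)))
        stop("patient labels are required for patient-wise simulation")
    cts <- as.matrix(assay(sc, "counts"))
    types <- sort(unique(sc$cell_type))
    pats <- unique(sc$patient)
    keep <- vapply(pats, function(p) sum(sc$patient == p) > 0, logical(1))
    if (!all(keep)) warning("skipping patients with zero cells")
    pats <- pats[keep]
    expr <- vapply(pats, function(p)
        rowSums(cts[, sc$patient == p, drop = FALSE]), numeric(nrow(cts)))
    dimnames(expr) <- list(rownames(cts), pats)
    P <- t(vapply(pats, function(p) {
        tab <- table(factor(sc$cell_type[sc$patient == p], levels = types))
        as.numeric(tab) / sum(tab)
    }, numeric(length(types))))
    dimnames(P) <- list(pats, types)
    prov <- lapply(pats, function(p) list(patient = p,
                                          cells = colnames(cts)[sc$patient == p]))
    names(prov) <- pats
    list(expression = expr, trueProportions = P, provenance = prov,
         strategy = "patient_sum")
}

#' Detected-gene coverage of pseudobulk samples
#'
#' @param expression genes x samples matrix (e.g. the \code{expression}
#'   element of a simulator result).
#' @return named integer vector: genes with expression > 0 per sample.
#' @export
geneCoverage <- function(expression) {
    expression <- as.matrix(expression)
    if (!length(expression)) stop("empty expression matrix")
    colSums(expression > 0)
}
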
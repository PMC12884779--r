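#' @importFrom Matrix readMM writeMM
#' @importFrom utils read.delim write.table head
NULL

#' Read a single-cell dataset from disk
#'
#' Accepts either a MatrixMarket triplet layout (\code{matrix.mtx} +
#' \code{genes.tsv} one identifier per line + \code{cells.tsv} annotation
#' table) or a dense layout (\code{expression.tsv} genes-as-rows with header
#' + \code{cells.tsv}). The cell annotation table must contain columns
#' \code{cell_id} and \code{cell_type}; \code{batch}, \code{tissue} and
#' \code{patient} are picked up when present.
#'
#' @param path directory containing the files.
#' @return an [ScReference-class].
#' @export
readScDataset <- function(path) {
    annPath <- file.path(path, "cells.tsv")
    if (!file.exists(annPath)) stop("missing cell annotation file: ", annPath)
    ann <- read.delim(annPath, stringsAsFactors = FALSE)
    if (!"cell_id" %in% colnames(ann)) stop("cells.tsv must have a 'cell_id' column")
    if (!"cell_type" %in% colnames(ann))
        stop("cells.tsv must have a 'cell_type' column (cell labels are inputs)")
    mtxPath <- file.path(path, "matrix.mtx")
    if (file.exists(mtxPath)) {
        m <- as.matrix(readMM(mtxPath))
        genes <- readLines(file.path(path, "genes.tsv"))
        if (length(genes) != nrow(m))
            stop("genes.tsv has ", length(genes), " entries but the matrix has ",
                 nrow(m), " rows")
        rownames(m) <- genes
        if (nrow(ann) != ncol(m))
            stop("annotation/matrix mismatch: ", nrow(ann), " cells annotated, ",
                 ncol(m), " columns in the matrix")
        colnames(m) <- ann$cell_id
    } else {
        densePath <- file.path(path, "expression.tsv")
        if (!file.exists(densePath))
            stop("neither matrix.mtx nor expression.tsv found in ", path)
        tab <- read.delim(densePath, row.names = 1, check.names = FALSE)
        m <- as.matrix(tab)
        missing <- setdiff(colnames(m), ann$cell_id)
        if (length(missing))
            stop("annotation missing for cell(s): ",
                 paste(head(missing, 3), collapse = ", "))
        ann <- ann[match(colnames(m), ann$cell_id), ]
    }
    ScReference(m, cell_type = ann$cell_type,
                batch = if ("batch" %in% colnames(ann)) ann$batch,
                tissue = if ("tissue" %in% colnames(ann)) ann$tissue,
                patient = if ("patient" %in% colnames(ann)) ann$patient)
}

#' Write a single-cell dataset in the layout [readScDataset()] reads
#'
#' @param sc an [ScReference-class].
#' @param path output directory (created if needed).
#' @param sparse write MatrixMarket (default) or a dense TSV.
#' @return the path, invisibly.
#' @export
writeScDataset <- function(sc, path, sparse = TRUE) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    cts <- assay(sc, "counts")
    if (sparse) {
        writeMM(methods::as(methods::as(as.matrix(cts), "dMatrix"), "CsparseMatrix"),
                file.path(path, "matrix.mtx"))
        writeLines(rownames(sc), file.path(path, "genes.tsv"))
    } else {
        write.table(as.matrix(cts), file.path(path, "expression.tsv"),
                    sep = "\t", quote = FALSE, col.names = NA)
    }
    ann <- as.data.frame(colData(sc))
    ann <- cbind(cell_id = colnames(sc), ann)
    write.table(ann, file.path(path, "cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a bulk expression table (genes as rows, samples as columns)
#'
#' @param path TSV/CSV file; the delimiter is inferred from the extension.
#' @return a [BulkExpression-class].
#' @export
readBulkMatrix <- function(path) {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    tab <- read.delim(path, row.names = 1, sep = sep, check.names = FALSE)
    BulkExpression(as.matrix(tab))
}

#' Write estimated proportions as a TSV
#'
#' Samples as rows, cell types as columns (panel order), fixed 6-decimal
#' formatting, plus a \code{degenerate} flag column.
#'
#' @param p a [ProportionEstimate-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeProportions <- function(p, path) {
    P <- proportions(p)
    out <- data.frame(sample_id = rownames(P),
                      format(P, nsmall = 6, digits = 1, scientific = FALSE,
                             trim = TRUE),
                      degenerate = degenerateFlags(p),
                      check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a proportions TSV written by [writeProportions()]
#'
#' @param path the file.
#' @return samples x cell types numeric matrix.
#' @export
readProportions <- function(path) {
    tab <- read.delim(path, check.names = FALSE)
    m <- as.matrix(tab[, setdiff(colnames(tab), c("sample_id", "degenerate")),
                       drop = FALSE])
    rownames(m) <- tab$sample_id
    m
}

knownConfigKeys <- c("sc_path", "bulk_path", "out_dir", "seed",
                     "n_hvg", "n_cells", "min_detected_genes",
                     "min_cells_per_gene", "k_neighbors", "diffusion_steps",
                     "confounder", "latent_dim", "hidden", "adv_hidden",
                     "lambda", "ae_epochs", "adv_epochs", "joint_rounds",
                     "batch_size", "learning_rate", "method", "labels_path")

#' Read and validate a pipeline configuration (JSON)
#'
#' Unknown keys are an error before any computation; every stochastic stage
#' derives its seed from the single master \code{seed}.
#'
#' @param path JSON file of configuration keys.
#' @return validated named list.
#' @export
readRunConfig <- function(path) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(cfg), knownConfigKeys)
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg
}

#' Run the full deconvolution pipeline
#'
#' preprocess -> train -> embed -> deconvolve, writing artifacts under
#' \code{cfg$out_dir}: the panel gene list, the trained-model history, the
#' reference panel, and the estimated proportions (plus a JSON sidecar with
#' the configuration). All randomness derives from \code{cfg$seed}, so two
#' runs with equal inputs and config produce byte-identical outputs.
#'
#' @param cfg list as returned by [readRunConfig()], or the path to one.
#'   \code{sc_path}, \code{bulk_path} and \code{out_dir} are required.
#' @return invisibly, a list with the model, panel, latents and proportions.
#' @export
runPipeline <- function(cfg) {
    if (is.character(cfg)) cfg <- readRunConfig(cfg)
    need <- c("sc_path", "bulk_path", "out_dir")
    miss <- setdiff(need, names(cfg))
    if (length(miss)) stop("config misses: ", paste(miss, collapse = ", "))
    g <- function(k, d) if (!is.null(cfg[[k]])) cfg[[k]] else d
    seed <- as.integer(g("seed", 1))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

    sc <- readScDataset(cfg$sc_path)
    bulk <- readBulkMatrix(cfg$bulk_path)
    prep <- preprocessReference(sc, rownames(bulk),
                                nHVG = g("n_hvg", 5000),
                                nCells = g("n_cells", 5000), seed = seed,
                                kNeighbors = g("k_neighbors", 15),
                                diffusionSteps = g("diffusion_steps", 3),
                                minDetectedGenes = g("min_detected_genes", 200),
                                minCellsPerGene = g("min_cells_per_gene", 3))
    writeLines(prep$panel, file.path(cfg$out_dir, "panel_genes.txt"))

    confName <- g("confounder", "batch")
    conf <- colData(prep$sc)[[confName]]
    if (is.null(conf)) stop("confounder column '", confName, "' not found")
    model <- trainAAE(prep$logcounts, stats::setNames(list(conf), confName),
                      latentDim = as.integer(g("latent_dim", 100)),
                      hidden = unlist(g("hidden", c(512, 256))),
                      advHidden = as.integer(g("adv_hidden", 64)),
                      lambda = g("lambda", 1),
                      aeEpochs = g("ae_epochs", 50),
                      advEpochs = g("adv_epochs", 20),
                      jointRounds = g("joint_rounds", 30),
                      batchSize = g("batch_size", 128),
                      lr = g("learning_rate", 1e-3), seed = seed)
    write.table(trainingHistory(model),
                file.path(cfg$out_dir, "training_history.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    cellLat <- encodeCells(model, prep$logcounts)
    panel <- buildReferencePanel(cellLat, prep$sc$cell_type)
    write.table(panelMatrix(panel), file.path(cfg$out_dir, "reference_panel.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)

    shared <- intersectGenes(prep$sc, bulk)
    bulkLog <- normalizeBulk(bulk, prep$panel, libraryGenes = shared)
    bulkLat <- embedBulk(model, bulkLog)
    props <- estimateProportions(panel, bulkLat, method = g("method", "boosted_linear"))
    writeProportions(props, file.path(cfg$out_dir, "proportions.tsv"))
    jsonlite::write_json(cfg, file.path(cfg$out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(model = model, panel = panel, bulkLatents = bulkLat,
                   proportions = props, prep = prep))
}
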
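# File formats: Matrix Market counts with gene/cell TSV sidecars, YAML
# configs. The on-disk orientation (genes or cells as matrix rows) is
# recorded in the cells sidecar-adjacent YAML and normalized on read.

#' Write an experiment to Matrix Market plus TSV sidecars
#'
#' Writes `matrix.mtx` (genes as rows), `genes.tsv` (column `gene_id`),
#' `cells.tsv` (columns `cell_id`, `treatment`, optional `ground_truth`)
#' and `experiment.yaml` recording the orientation and, when present, the
#' simulation design parameters.
#'
#' @param x A `SingleCellExperiment` with assay `"counts"` and `colData`
#'   column `treatment` (and optionally `ground_truth`).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeExperiment <- function(x, dir) {
  if (!is(x, "SummarizedExperiment"))
    stop("x must be a SingleCellExperiment", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(x, "counts")
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(gene_id = rownames(counts)),
              file.path(dir, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cells <- data.frame(cell_id = colnames(counts),
                      treatment = cd$treatment)
  if (!is.null(cd$ground_truth)) cells$ground_truth <- cd$ground_truth
  write.table(cells, file.path(dir, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(orientation = "genes_by_cells",
               n_genes = nrow(counts), n_cells = ncol(counts))
  design <- S4Vectors::metadata(x)$design
  if (!is.null(design))
    meta$design <- design[!vapply(design, is.numeric, logical(1)) |
                            lengths(design) == 1]
  yaml::write_yaml(meta, file.path(dir, "experiment.yaml"))
  invisible(dir)
}

#' Read an experiment from Matrix Market plus TSV sidecars
#'
#' Inverse of [writeExperiment()]. Dimensions are validated against both
#' sidecars, duplicate identifiers rejected, and the matrix orientation
#' (from `experiment.yaml`, or inferred from the sidecar lengths)
#' normalized to genes-by-cells.
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return A `SingleCellExperiment`.
#' @export
readExperiment <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(Matrix::readMM(paths[1]))
  genes <- read.delim(paths[2], stringsAsFactors = FALSE)
  cells <- read.delim(paths[3], stringsAsFactors = FALSE)
  if (!"gene_id" %in% colnames(genes))
    stop("genes.tsv must have a gene_id column", call. = FALSE)
  for (col in c("cell_id", "treatment"))
    if (!col %in% colnames(cells))
      stop("cells.tsv must have a ", col, " column", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in genes.tsv", call. = FALSE)
  if (anyDuplicated(cells$cell_id))
    stop("duplicate cell ids in cells.tsv", call. = FALSE)

  orientation <- NULL
  metaPath <- file.path(dir, "experiment.yaml")
  if (file.exists(metaPath))
    orientation <- yaml::read_yaml(metaPath)$orientation
  if (is.null(orientation)) {
    orientation <- if (nrow(m) == nrow(genes) && ncol(m) == nrow(cells))
      "genes_by_cells"
    else if (nrow(m) == nrow(cells) && ncol(m) == nrow(genes))
      "cells_by_genes"
    else
      stop("matrix dimensions match neither sidecar orientation",
           call. = FALSE)
  }
  if (orientation == "cells_by_genes") m <- t(m)
  if (nrow(m) != nrow(genes) || ncol(m) != nrow(cells))
    stop(sprintf(
      "dimension mismatch: matrix %d x %d vs %d genes, %d cells",
      nrow(m), ncol(m), nrow(genes), nrow(cells)), call. = FALSE)
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  cd <- S4Vectors::DataFrame(treatment = cells$treatment,
                             row.names = cells$cell_id)
  if ("ground_truth" %in% colnames(cells))
    cd$ground_truth <- cells$ground_truth
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = cd)
}

.configKeys <- c("scenario", "nGenes", "cellsPerPop", "popSizes",
                 "avgMarkers", "percPerturbed", "stimMultiplier",
                 "meanShape", "meanScale", "dispersion", "dropoutBeta",
                 "variant", "k", "gamma", "sigma", "lambda", "eta0",
                 "tol", "maxIter", "subsampleThreshold", "subsampleSize",
                 "normalize", "logTransform", "nHVG", "control",
                 "treatment", "seed", "out")

#' Read or write a run configuration
#'
#' YAML documents mirroring the arguments of [simulatePerturbation()] and
#' [identifyStates()] plus a master seed and output directory. Unknown
#' keys are rejected so typos fail loudly; [writeRunConfig()] is used by
#' the pipeline to write back the fully resolved configuration alongside
#' results.
#'
#' @param path YAML file path.
#' @param config Named list of configuration values.
#' @return `readRunConfig()`: a named list; `writeRunConfig()`: `path`,
#'   invisibly.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  unknown <- setdiff(names(config), .configKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write state labels and gene weights as TSV
#'
#' `writeStateLabels()` writes `cell_id`, `treatment`, `label`;
#' `writeGeneWeights()` writes `gene_id`, `weight` (one file per
#' treatment plus the pooled vector when given a [StateAssignment-class]).
#'
#' @param result A [StateAssignment-class] object.
#' @param treatment Per-cell treatment vector, named by cell id.
#' @param path,dir Output file / directory.
#' @return The path(s) written, invisibly.
#' @export
writeStateLabels <- function(result, treatment, path) {
  labs <- stateLabels(result)
  df <- data.frame(cell_id = names(labs),
                   treatment = treatment[names(labs)],
                   label = unname(labs))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStateLabels
#' @export
writeGeneWeights <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(result@weights)) {
    w <- geneWeights(result@weights[[nm]])
    p <- file.path(dir, paste0("weights_", nm, ".tsv"))
    write.table(data.frame(gene_id = names(w), weight = unname(w)),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  w <- pooledWeights(result)
  p <- file.path(dir, "weights_pooled.tsv")
  write.table(data.frame(gene_id = names(w), weight = unname(w)),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}
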
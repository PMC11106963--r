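## Tab-separated I/O for count matrices, sample sheets, gene annotation
## and simulation bundles. All tables are plain TSV with a header row;
## result tables written by the pipeline carry a versioned schema
## comment line.

.SCHEMA_VERSION <- "1"

#' Read a gene x sample count table
#'
#' Tab-separated, header row, first column the gene id.
#'
#' @param path File path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
readCounts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("count table needs a gene id column and samples")
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0))
    stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

.readSheet <- function(path, required, idCol) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  miss <- setdiff(required, colnames(tab))
  if (length(miss))
    stop(basename(path), " lacks column(s): ",
         paste(miss, collapse = ", "))
  dup <- unique(tab[[idCol]][duplicated(tab[[idCol]])])
  if (length(dup))
    stop("duplicate ", idCol, ": ", paste(dup, collapse = ", "))
  tab
}

#' Read a sample sheet
#'
#' Required columns: `sample_id`, `assay`, `genotype`, `zt`,
#' `replicate`, `library_size`.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
readSamples <- function(path) {
  .readSheet(path, c("sample_id", "assay", "genotype", "zt", "replicate",
                     "library_size"), "sample_id")
}

#' Read a gene annotation table
#'
#' Required columns: `gene_id`, `cds_len`, `exon_len`, `intron_len`
#' (a `class` column is kept when present).
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
readGenes <- function(path) {
  .readSheet(path, c("gene_id", "cds_len", "exon_len", "intron_len"),
             "gene_id")
}

#' Assemble a CountMatrix from files
#'
#' @param countsPath,samplesPath,genesPath TSV paths (see [readCounts()],
#'   [readSamples()], [readGenes()]).
#' @param assayType `"rpf"`, `"rna_exon"`, or `"rna_intron"`; selects
#'   the feature length (CDS, exon, intron) and the sample-sheet rows.
#' @return A [CountMatrix].
#' @export
countMatrixFromFiles <- function(countsPath, samplesPath, genesPath,
                                 assayType) {
  assayType <- match.arg(assayType, .ASSAY_TYPES)
  cts <- readCounts(countsPath)
  samples <- readSamples(samplesPath)
  genes <- readGenes(genesPath)
  samples <- samples[samples$assay == assayType, , drop = FALSE]
  missing <- setdiff(colnames(cts), samples$sample_id)
  if (length(missing))
    stop("sample(s) in count matrix absent from sample sheet: ",
         paste(missing, collapse = ", "))
  samples <- samples[match(colnames(cts), samples$sample_id), ]
  gmiss <- setdiff(rownames(cts), genes$gene_id)
  if (length(gmiss))
    stop("gene(s) in count matrix absent from annotation: ",
         paste(gmiss, collapse = ", "))
  genes <- genes[match(rownames(cts), genes$gene_id), ]
  len <- switch(assayType, rpf = genes$cds_len, rna_exon = genes$exon_len,
                rna_intron = genes$intron_len)
  extra <- intersect("class", colnames(genes))
  countMatrix(cts,
              samples[, c("genotype", "zt", "replicate", "library_size")],
              lengthBp = len, assayType = assayType,
              geneData = if (length(extra))
                genes[, extra, drop = FALSE] else NULL)
}

.writeTsv <- function(x, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# schema: %s v%s", schema, .SCHEMA_VERSION), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated experiment to disk
#'
#' Writes `counts_rpf.tsv`, `counts_rna_exon.tsv`,
#' `counts_rna_intron.tsv`, `samples.tsv`, `genes.tsv`, `truth.tsv`, and
#' the generating configuration as `config.yaml` (seed included).
#'
#' @param sim Result of [simulateExperiment()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (layer in names(sim$counts)) {
    cts <- assay(sim$counts[[layer]], "counts")
    tab <- data.frame(gene_id = rownames(cts), cts, check.names = FALSE)
    .writeTsv(tab, file.path(dir, sprintf("counts_%s.tsv", layer)),
              sprintf("counts_%s: gene_id + one integer column per sample",
                      layer))
  }
  .writeTsv(sim$samples, file.path(dir, "samples.tsv"),
            "samples: sample_id assay genotype zt replicate library_size")
  .writeTsv(sim$genes, file.path(dir, "genes.tsv"),
            "genes: gene_id class cds_len exon_len intron_len")
  .writeTsv(sim$truth, file.path(dir, "truth.tsv"),
            "truth: per-gene class, mode, realized layer amplitudes/phases")
  yaml::write_yaml(configAsList(sim$config),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Serialize a SimConfig to a plain list (for YAML round-tripping)
#'
#' @param config A [SimConfig].
#' @return Nested plain list.
#' @export
configAsList <- function(config) {
  list(
    n_genes_per_class = config@nGenesPerClass,
    timepoints = config@timepoints,
    n_replicates = config@nReplicates,
    library_size = config@librarySize,
    dispersion = config@dispersion,
    noise = config@noise,
    seed = config@seed,
    genotypes = config@genotypes,
    amplitude_scale = config@amplitudeScale,
    feeding = list(name = config@feeding@name,
                   dark_fraction = config@feeding@darkFraction),
    gene_classes = lapply(config@geneClasses, function(cls) {
      list(name = cls@name,
           baseline_rpkm = as.list(cls@baselineRpkm),
           baseline_log2_te = cls@baselineLog2TE,
           rhythms = cls@rhythms,
           ko_effects = lapply(cls@koEffects, function(e)
             lapply(e, as.list)),
           self_ko = cls@selfKO,
           lengths = as.list(cls@lengths),
           size_factor = cls@sizeFactor,
           spread_log2 = cls@spreadLog2)
    }))
}

#' Rebuild a SimConfig from a plain list (e.g. parsed YAML)
#'
#' @param x Nested list as produced by [configAsList()]; a
#'   `gene_classes` entry of `NULL` falls back to [defaultGenePanel()].
#' @return A [SimConfig].
#' @export
configFromList <- function(x) {
  classes <- if (is.null(x$gene_classes)) defaultGenePanel() else
    lapply(x$gene_classes, function(cls) {
      geneClassSpec(
        name = cls$name,
        intronRpkm = cls$baseline_rpkm$intron,
        exonRpkm = cls$baseline_rpkm$exon,
        baselineLog2TE = cls$baseline_log2_te,
        intronRhythm = cls$rhythms$intron,
        exonRhythm = cls$rhythms$exon,
        rpfRhythm = cls$rhythms$rpf,
        koEffects = lapply(cls$ko_effects, function(e)
          lapply(e, unlist)),
        selfKO = if (is.null(cls$self_ko)) NA_character_ else cls$self_ko,
        lengths = unlist(cls$lengths),
        sizeFactor = cls$size_factor %||% 1,
        spreadLog2 = cls$spread_log2 %||% 0)
    })
  feeding <- if (is.null(x$feeding)) feedingRegime("night_restricted")
    else feedingRegime(x$feeding$name, x$feeding$dark_fraction)
  simConfig(
    nGenesPerClass = x$n_genes_per_class %||% 10,
    timepoints = x$timepoints %||% seq(0, 22, by = 2),
    nReplicates = x$n_replicates %||% 2,
    librarySize = x$library_size %||% 1e7,
    dispersion = x$dispersion %||% 20,
    noise = x$noise %||% "nb",
    seed = x$seed %||% 1L,
    genotypes = x$genotypes %||% "WT",
    feeding = feeding,
    geneClasses = classes,
    amplitudeScale = x$amplitude_scale %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration file
#'
#' YAML with either a `simulation:` block (parameters for
#' [configFromList()]) or a `data:` block with paths `counts_rpf`,
#' `counts_rna_exon`, `counts_rna_intron`, `samples`, `genes`, plus an
#' optional `parameters:` block (`pseudocount`, `alpha`, `min_fold`,
#' `min_delta`, `k`, `n_init`, `seed`).
#'
#' @param path YAML file.
#' @return List with elements `simulation` (a [SimConfig] or `NULL`),
#'   `data` (paths or `NULL`), and `parameters`.
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$simulation) && is.null(x$data))
    stop("config needs a 'simulation' or a 'data' block")
  if (!is.null(x$simulation) && !is.null(x$data))
    stop("config cannot have both 'simulation' and 'data' blocks")
  list(simulation = if (!is.null(x$simulation))
         configFromList(x$simulation) else NULL,
       data = x$data,
       parameters = x$parameters %||% list())
}
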
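# Plain-text readers/writers for the pipeline's interchange formats:
# counts and sample metadata as TSV, flattened gene models as GFF3
# (exonic_part records), SNPs as BED or 1-based TSV, ground truth as JSON.

#' Write an ExonCountSet as TSV files
#'
#' @param ecs an [ExonCountSet-class].
#' @param countsFile path for the count table (exon_id, gene_id, one column
#'   per sample).
#' @param metaFile path for the sample metadata table.
#' @return Invisibly, the two paths.
#' @export
writeCounts <- function(ecs, countsFile, metaFile) {
    cts <- assay(ecs, "counts")
    df <- data.frame(exon_id = exonIds(ecs), gene_id = geneIds(ecs),
                     cts, check.names = FALSE)
    write.table(df, countsFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cd <- as.data.frame(colData(ecs))
    cd <- cbind(sample = rownames(cd), cd)
    write.table(cd, metaFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(countsFile, metaFile))
}

#' Read an ExonCountSet from TSV files
#'
#' @param countsFile count table written by [writeCounts()].
#' @param metaFile sample metadata table.
#' @param models exon `GRanges` (e.g. from [readGeneModels()]); rows are
#'   matched to counts by `exon_id`.
#' @return An [ExonCountSet-class].
#' @export
readExonCounts <- function(countsFile, metaFile, models) {
    df <- read.delim(countsFile, check.names = FALSE,
                     stringsAsFactors = FALSE)
    meta <- read.delim(metaFile, stringsAsFactors = FALSE)
    rownames(meta) <- meta$sample
    meta$sample <- NULL
    cts <- as.matrix(df[, rownames(meta), drop = FALSE])
    rownames(cts) <- df$exon_id
    m <- models[match(df$exon_id, models$exon_id)]
    ExonCountSet(cts, m, meta)
}

#' Write gene models as GFF3
#'
#' Writes one `exonic_part` record per exon (1-based inclusive
#' coordinates, per the GFF dialect) with `gene_id`, `exon_id` and
#' `exon_number` attributes.
#'
#' @param models exon `GRanges` from [simulateGeneModels()].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeGeneModels <- function(models, file) {
    gr <- granges(models)
    mcols(gr)$source <- "spliceDyn"
    mcols(gr)$type <- "exonic_part"
    mcols(gr)$gene_id <- models$gene_id
    mcols(gr)$exon_id <- models$exon_id
    mcols(gr)$exon_number <- models$exon_rank
    rtracklayer::export(gr, file, format = "gff3")
    invisible(file)
}

#' Read gene models from GFF3
#'
#' @param file a GFF3 file written by [writeGeneModels()] (or any GFF3 of
#'   exon/exonic_part records with `gene_id` attributes).
#' @return Exon `GRanges` with `gene_id`, `exon_id`, `exon_rank`.
#' @export
readGeneModels <- function(file) {
    gr <- rtracklayer::import(file, format = "gff3")
    gr <- gr[gr$type %in% c("exonic_part", "exon")]
    stopifnot(!is.null(gr$gene_id))
    out <- granges(gr)
    mcols(out)$gene_id <- as.character(gr$gene_id)
    rank <- if (!is.null(gr$exon_number)) as.integer(gr$exon_number)
        else stats::ave(start(out), mcols(out)$gene_id,
                        FUN = function(s) rank(s, ties.method = "first"))
    mcols(out)$exon_rank <- rank
    mcols(out)$exon_id <- if (!is.null(gr$exon_id)) as.character(gr$exon_id)
        else sprintf("%s:E%03d", mcols(out)$gene_id, rank)
    names(out) <- out$exon_id
    out
}

#' Write SNP positions as 3-column BED
#'
#' @param snps width-1 `GRanges` of SNP positions.
#' @param file output path (BED, 0-based half-open).
#' @return Invisibly, `file`.
#' @export
writeSnps <- function(snps, file) {
    rtracklayer::export(granges(snps), file, format = "bed")
    invisible(file)
}

#' Read SNP positions
#'
#' @param file input path.
#' @param format "bed" (0-based half-open; converted on import) or "tsv"
#'   (1-based, columns chrom and pos).
#' @return Width-1 `GRanges`.
#' @export
readSnps <- function(file, format = c("bed", "tsv")) {
    format <- match.arg(format)
    if (format == "bed") {
        granges(rtracklayer::import(file, format = "bed"))
    } else {
        df <- read.delim(file, stringsAsFactors = FALSE)
        stopifnot(all(c("chrom", "pos") %in% colnames(df)))
        GRanges(df$chrom, IRanges(as.integer(df$pos), width = 1L))
    }
}

#' Write or read simulation ground truth as JSON
#'
#' @param truth truth list from [simulateCounts()].
#' @param file path.
#' @return `writeTruth` invisibly returns `file`; `readTruth` the list.
#' @export
writeTruth <- function(truth, file) {
    truth$params <- truth$params[!vapply(truth$params, is.null, logical(1))]
    jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    invisible(file)
}

#' @rdname writeTruth
#' @export
readTruth <- function(file) {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    x$dsExons <- as.data.frame(x$dsExons, stringsAsFactors = FALSE)
    x$deGenes <- as.data.frame(x$deGenes, stringsAsFactors = FALSE)
    x
}
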
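# Plain-file interfaces. Coordinates are BED-convention (0-based half-open)
# on disk and GRanges-convention (1-based closed) in memory; rtracklayer
# performs the conversion at the boundary.

#' Write / read a guide count table (TSV)
#'
#' Columns: `guide_id`, `gene_id`, `cell_line`, `timepoint`, `replicate`,
#' `count`.
#'
#' @param counts guide count `data.frame`.
#' @param path file path.
#' @return `readGuideCounts` returns the `data.frame`.
#' @export
writeGuideCounts <- function(counts, path) {
    .checkGuideTable(counts)
    write.table(counts[, c("guide_id", "gene_id", "cell_line", "timepoint",
                           "replicate", "count")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGuideCounts
#' @export
readGuideCounts <- function(path) {
    out <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    .checkGuideTable(out)
    out
}

#' Write / read crosslink sites or peaks as BED6
#'
#' Sites carry `name = condition:replicate` and `score` = crosslink count;
#' peaks carry `name` = comma-joined condition membership.
#'
#' @param gr a `GRanges`; for sites, with `condition`/`replicate`/`score`
#'   metadata columns.
#' @param path file path.
#' @return `readSitesBed` returns a `GRanges` with `condition`, `replicate`
#'   and `score` columns reconstructed from the BED name/score fields.
#' @export
writeSitesBed <- function(gr, path) {
    out <- gr
    nm <- if (!is.null(gr$condition) && !is.null(gr$replicate))
        paste0(gr$condition, ":", gr$replicate)
    else if (!is.null(gr$name)) gr$name
    else as.character(seq_along(gr))
    sc <- if (!is.null(gr$score)) gr$score else 0
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(name = nm, score = sc)
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' @rdname writeSitesBed
#' @export
readSitesBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(gr$name) && all(grepl(":", gr$name))) {
        parts <- strsplit(gr$name, ":", fixed = TRUE)
        gr$condition <- vapply(parts, `[`, character(1), 1L)
        gr$replicate <- as.integer(vapply(parts, `[`, character(1), 2L))
    }
    gr
}

#' Write / read peaks as BED6 with condition membership in the name
#' @param peaks peak `GRanges`; `conditions` optional metadata column.
#' @param path file path.
#' @export
writePeaksBed <- function(peaks, path) {
    out <- peaks
    nm <- if (!is.null(peaks$conditions)) peaks$conditions
          else rep(".", length(peaks))
    sc <- if (!is.null(peaks$n_sites)) peaks$n_sites else 0
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(name = nm, score = sc)
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Write / read a transcript feature annotation (GTF)
#'
#' Feature types `five_prime_utr` / `CDS` / `three_prime_utr` / `exon` with
#' `gene_id`, `transcript_id` and `gene_biotype` attributes.
#'
#' @param annotation feature `GRanges`.
#' @param path file path.
#' @return `readAnnotationGtf` returns the feature `GRanges` with the
#'   package's in-memory column names (`type`, `gene_id`, `transcript_id`,
#'   `biotype`).
#' @export
writeAnnotationGtf <- function(annotation, path) {
    out <- annotation
    out$gene_biotype <- out$biotype
    out$biotype <- NULL
    out$source <- "ncRBPtools"
    out$phase <- ifelse(out$type == "CDS", 0L, NA_integer_)
    rtracklayer::export(out, path, format = "GTF")
    invisible(path)
}

#' @rdname writeAnnotationGtf
#' @export
readAnnotationGtf <- function(path) {
    gr <- rtracklayer::import(path, format = "GTF")
    keep <- intersect(c("type", "gene_id", "transcript_id", "gene_biotype"),
                      names(S4Vectors::mcols(gr)))
    S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep, drop = FALSE]
    if ("gene_biotype" %in% keep) {
        gr$biotype <- gr$gene_biotype
        gr$gene_biotype <- NULL
    }
    gr$type <- as.character(gr$type)
    validateAnnotation(gr)
    gr
}

#' Write / read an expression count matrix with a sample metadata sidecar
#'
#' The counts go to a TSV (genes x samples, first column `gene_id`), the
#' sample metadata (`sample`, `group`, `condition`, `fraction`,
#' `replicate`) to a CSV next to it.
#'
#' @param se `SummarizedExperiment` with a `counts` assay.
#' @param countsPath,metaPath file paths.
#' @return `readExpression` returns the `SummarizedExperiment`.
#' @export
writeExpression <- function(se, countsPath, metaPath) {
    m <- SummarizedExperiment::assay(se, "counts")
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(df, countsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    cd <- data.frame(sample = rownames(cd), cd, check.names = FALSE,
                     row.names = NULL)
    cd$sample_id <- NULL
    write.csv(cd, metaPath, row.names = FALSE, quote = FALSE)
    invisible(countsPath)
}

#' @rdname writeExpression
#' @export
readExpression <- function(countsPath, metaPath) {
    df <- read.delim(countsPath, check.names = FALSE, comment.char = "#")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene_id
    cd <- read.csv(metaPath, stringsAsFactors = FALSE)
    rownames(cd) <- cd$sample
    cd <- cd[colnames(m), , drop = FALSE]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(cd))
}

#' Write an LFC table (gene, log2fc) as TSV
#' @param de `data.frame` with `gene_id` and `log2fc`.
#' @param path file path.
#' @export
writeLfcTable <- function(de, path) {
    write.table(de[, c("gene_id", "log2fc")], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an LFC table into a named vector
#' @param path TSV with columns `gene_id` (or `gene`) and `log2fc`.
#' @return named numeric vector gene -> log2 fold change.
#' @export
readLfcTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    idCol <- intersect(c("gene_id", "gene"), names(df))[1L]
    setNames(df$log2fc, df[[idCol]])
}
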
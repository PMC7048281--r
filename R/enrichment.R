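#' Load a miRNA-to-target map
#'
#' Two-column (miRNA id, target gene) delimited file, miRTarBase-style, with
#' an optional third evidence column that can be filtered (e.g. keep only
#' "strong" support).  Duplicate (miRNA, gene) pairs are collapsed.  An
#' optional homologue map (two columns: from, to) translates miRNA ids
#' (e.g. bta to hsa names); identity mapping by default.
#'
#' @param path TSV path (header optional: detected when the first line's
#'   second field is not a gene-looking duplicate of itself; simplest is to
#'   supply a header \code{mirna_id<TAB>gene_id[<TAB>evidence]}).
#' @param evidenceFilter optional value the third column must equal
#'   (case-insensitive) for a pair to be kept.
#' @param homologMap optional \code{data.frame}/TSV path with columns
#'   \code{from}, \code{to} translating miRNA ids before collapsing.
#' @return named list: miRNA id -> character vector of target genes.
#' @export
readTargetMap <- function(path, evidenceFilter = NULL, homologMap = NULL) {
    df <- if (is.data.frame(path)) path else
        utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
    if (ncol(df) < 2)
        stop("target map needs at least two columns (miRNA, gene)",
             call. = FALSE)
    mir <- as.character(df[[1]]); gene <- as.character(df[[2]])
    if (!is.null(evidenceFilter)) {
        if (ncol(df) < 3)
            stop("evidenceFilter given but the map has no evidence column",
                 call. = FALSE)
        keep <- tolower(as.character(df[[3]])) == tolower(evidenceFilter)
        mir <- mir[keep]; gene <- gene[keep]
    }
    if (!is.null(homologMap)) {
        if (is.character(homologMap) && length(homologMap) == 1)
            homologMap <- readTsv(homologMap)
        m <- match(mir, as.character(homologMap[[1]]))
        mir[!is.na(m)] <- as.character(homologMap[[2]])[m[!is.na(m)]]
    }
    keep <- !duplicated(paste0(mir, "\r", gene))
    lapply(split(gene[keep], mir[keep]), unique)
}

#' Read GMT pathway gene sets
#'
#' @param path GMT file (one pathway per line: name, description, genes).
#' @return named list: pathway -> character vector of member genes; empty
#'   gene sets are dropped.
#' @export
readGmt <- function(path) {
    sets <- fgsea::gmtPathways(path)
    sets <- lapply(sets, unique)
    sets[lengths(sets) > 0]
}

#' Pathway over-representation for significant miRNAs
#'
#' Implements the gene-level collapse that avoids over-counting single
#' miRNAs with many targets in the same pathway: the query gene set is the
#' UNION of the targets of all significant miRNAs, so a gene targeted by
#' several miRNAs contributes once.  The gene universe is the set of genes
#' appearing both in the target map and in at least one pathway; query and
#' pathways are restricted to it.  Each pathway is tested with an upper-tail
#' hypergeometric test (probability of an overlap at least as large as
#' observed), adjusted across pathways by Benjamini-Hochberg, and ranked by
#' ascending p.
#'
#' @param mirnas character vector of significant miRNA ids.
#' @param targetMap named list from \code{\link{readTargetMap}}.
#' @param pathways named list from \code{\link{readGmt}}.
#' @return \code{data.frame} with one row per pathway: \code{pathway},
#'   \code{overlap} (k), \code{pathway_size} (K, within universe),
#'   \code{query_size} (n), \code{universe_size} (N), \code{pvalue},
#'   \code{padj}, \code{genes} (overlap genes, comma-separated),
#'   \code{mirnas} (contributing miRNAs, comma-separated).
#' @export
pathwayEnrichment <- function(mirnas, targetMap, pathways) {
    known <- mirnas %in% names(targetMap)
    if (any(!known))
        warning("miRNA(s) absent from the target map, skipped: ",
                paste(mirnas[!known], collapse = ", "))
    mirnas <- mirnas[known]
    universe <- intersect(unique(unlist(targetMap, use.names = FALSE)),
                          unique(unlist(pathways, use.names = FALSE)))
    query <- intersect(unique(unlist(targetMap[mirnas], use.names = FALSE)),
                       universe)
    if (length(query) == 0)
        stop("no significant miRNA has a mapped target in the universe",
             call. = FALSE)
    N <- length(universe); n <- length(query)
    res <- lapply(names(pathways), function(pw) {
        genes <- intersect(pathways[[pw]], universe)
        K <- length(genes)
        hitGenes <- intersect(query, genes)
        k <- length(hitGenes)
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        contrib <- mirnas[vapply(mirnas, function(m)
            length(intersect(targetMap[[m]], hitGenes)) > 0, logical(1))]
        data.frame(pathway = pw, overlap = k, pathway_size = K,
                   query_size = n, universe_size = N, pvalue = p,
                   genes = paste(sort(hitGenes), collapse = ","),
                   mirnas = paste(sort(contrib), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$padj <- stats::p.adjust(out$pvalue, method = "BH")
    out <- out[order(out$pvalue, out$pathway), , drop = FALSE]
    rownames(out) <- NULL
    out[, c("pathway", "overlap", "pathway_size", "query_size",
            "universe_size", "pvalue", "padj", "genes", "mirnas")]
}

#' Top-n summary of an enrichment table
#'
#' @param enrichment result of \code{\link{pathwayEnrichment}}.
#' @param n number of pathways to keep (default 20).
#' @return the first \code{n} rows (already ranked by p-value).
#' @export
topEnrichment <- function(enrichment, n = 20L) {
    utils::head(enrichment, n)
}
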
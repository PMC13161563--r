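#' Read a differential-expression table
#'
#' Expects the standard DE-tool export layout: columns `gene_id`,
#' `log2FoldChange`, `pvalue`, `padj` (tab-separated). Already-normalized
#' column names (`log2fc`) are accepted.
#'
#' @param path TSV path.
#' @return Data frame with columns `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @export
read_de_table <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    if ("log2FoldChange" %in% names(d))
        names(d)[names(d) == "log2FoldChange"] <- "log2fc"
    need <- c("gene_id", "log2fc", "pvalue", "padj")
    if (!all(need %in% names(d)))
        stop("DE table must have columns gene_id, log2FoldChange, pvalue, padj")
    if (anyDuplicated(d$gene_id)) stop("duplicate gene_id in DE table")
    d[need]
}

normalize_de <- function(x) {
    if (is.character(x) && length(x) == 1) return(read_de_table(x))
    x <- as.data.frame(x)
    if ("log2FoldChange" %in% names(x))
        names(x)[names(x) == "log2FoldChange"] <- "log2fc"
    stopifnot(all(c("gene_id", "log2fc") %in% names(x)))
    x
}

#' Genes significant in both differential-expression comparisons
#'
#' @param table_treated,table_untreated DE tables (data frames or TSV
#'   paths; see [read_de_table()]): treated-vs-reference and
#'   untreated-vs-reference.
#' @param alpha Significance threshold (default 0.05).
#' @param criterion `"padj"` (default, multiplicity-adjusted) or
#'   `"pvalue"`.
#' @return Character vector of shared significant gene ids; attribute
#'   `n_dropped_na` counts genes dropped for missing effect or
#'   significance values.
#' @export
shared_significant <- function(table_treated, table_untreated, alpha = 0.05,
                               criterion = c("padj", "pvalue")) {
    criterion <- match.arg(criterion)
    t1 <- normalize_de(table_treated)
    t2 <- normalize_de(table_untreated)
    for (t in list(t1, t2))
        if (!criterion %in% names(t))
            stop("DE table lacks the chosen significance column: ", criterion)
    sig <- function(t) {
        ok <- !is.na(t[[criterion]]) & !is.na(t$log2fc)
        t$gene_id[ok & t[[criterion]] < alpha]
    }
    dropped <- sum(is.na(t1[[criterion]]) | is.na(t1$log2fc)) +
        sum(is.na(t2[[criterion]]) | is.na(t2$log2fc))
    out <- intersect(sig(t1), sig(t2))
    attr(out, "n_dropped_na") <- dropped
    out
}

#' Expression-restoration concordance between two DE comparisons
#'
#' Intersects two differential-expression tables on genes significant in
#' both, computes the Pearson correlation of their log2 fold changes, and
#' counts genes whose direction of change is reversed between the
#' comparisons (treatment shifting expression back toward the reference).
#' A strong negative correlation between treated-vs-healthy and
#' untreated-vs-healthy effects indicates restoration of the healthy
#' expression profile.
#'
#' @inheritParams shared_significant
#' @return Object of class `"restoration_result"`: list with
#'   `n_shared_significant`, `pearson_r`, `p_of_r`, `n_reversed`, `n_zero`
#'   (genes with a fold change of exactly 0, neither concordant nor
#'   reversed), `reversed_gene_ids` and the per-gene `shared_table`.
#'   `pearson_r` is `NA` with `r_defined = FALSE` for fewer than 3 shared
#'   genes or zero-variance effects.
#' @export
restoration <- function(table_treated, table_untreated, alpha = 0.05,
                        criterion = c("padj", "pvalue")) {
    criterion <- match.arg(criterion)
    t1 <- normalize_de(table_treated)
    t2 <- normalize_de(table_untreated)
    genes <- shared_significant(t1, t2, alpha = alpha, criterion = criterion)
    x <- t1$log2fc[match(genes, t1$gene_id)]
    y <- t2$log2fc[match(genes, t2$gene_id)]
    sgn <- sign(x) * sign(y)
    reversed <- genes[sgn < 0]
    n_zero <- sum(sgn == 0)
    r <- p <- NA_real_
    r_defined <- FALSE
    if (length(genes) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0) {
        ct <- cor.test(x, y, method = "pearson")
        r <- unname(ct$estimate)
        p <- ct$p.value
        r_defined <- TRUE
    }
    structure(list(
        n_shared_significant = length(genes),
        pearson_r = r, p_of_r = p, r_defined = r_defined,
        n_reversed = length(reversed), n_zero = n_zero,
        reversed_gene_ids = reversed,
        n_dropped_na = attr(genes, "n_dropped_na"),
        shared_table = data.frame(gene_id = genes, log2fc_treated = x,
                                  log2fc_untreated = y,
                                  reversed = sgn < 0,
                                  stringsAsFactors = FALSE),
        params = list(alpha = alpha, criterion = criterion)),
        class = "restoration_result")
}

#' @export
print.restoration_result <- function(x, ...) {
    cat("restoration_result:", x$n_shared_significant,
        "genes significant in both comparisons\n")
    if (x$r_defined)
        cat(sprintf("  Pearson r = %.4f (P = %.3g)\n", x$pearson_r, x$p_of_r))
    else cat("  Pearson r undefined (<3 genes or zero variance)\n")
    cat(sprintf("  %d genes reversed toward the reference, %d with zero effect\n",
                x$n_reversed, x$n_zero))
    invisible(x)
}

#' Write restoration results (per-gene TSV plus JSON summary)
#'
#' @param result A [restoration()] result.
#' @param tsv Per-gene shared table output path.
#' @param json Optional JSON summary path.
#' @return Invisibly, `tsv`.
#' @export
write_restoration <- function(result, tsv, json = NULL) {
    write_tsv_report(result$shared_table, tsv, params = c(
        result$params,
        list(n_shared_significant = result$n_shared_significant,
             pearson_r = result$pearson_r, p_of_r = result$p_of_r,
             n_reversed = result$n_reversed)))
    if (!is.null(json)) {
        s <- result
        s$shared_table <- NULL
        jsonlite::write_json(unclass(s), json, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE, force = TRUE)
    }
    invisible(tsv)
}
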
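#' Build the genomic target site of a guide
#'
#' The target site is the DNA reverse complement of the guide: the sequence
#' a perfectly complementary transcript or genomic segment would carry.
#'
#' @param guide A [guide_strand()] or nucleotide string (RNA or DNA).
#' @return Object of class `"target_site"`: list with `guide_name` and
#'   `site_sequence` (DNA).
#' @examples
#' make_target_site(a2_guide())$site_sequence  # "GCAGCAGCAGCTGCAGCAG"
#' @export
make_target_site <- function(guide) {
    seq <- as_guide_sequence(guide)
    name <- if (inherits(guide, "guide_strand")) guide$name else "guide"
    structure(list(guide_name = name,
                   site_sequence = revcomp_dna(normalize_seq(seq, "dna"))),
              class = "target_site")
}

as_dna_stringset <- function(sequences) {
    if (is(sequences, "DNAStringSet")) return(sequences)
    if (length(sequences) == 0) return(Biostrings::DNAStringSet())
    if (is.character(sequences) && length(sequences) == 1 &&
        file.exists(sequences) && is.null(names(sequences)))
        return(Biostrings::readDNAStringSet(sequences))
    if (is.character(sequences)) {
        if (is.null(names(sequences)))
            names(sequences) <- paste0("seq", seq_along(sequences))
        return(Biostrings::DNAStringSet(toupper(chartr("U", "T", sequences))))
    }
    stop("sequences must be a DNAStringSet, a named character vector, ",
         "or a FASTA path")
}

empty_hits <- function() {
    data.frame(sequence_id = character(), strand = character(),
               start = integer(), end = integer(),
               mismatch_count = integer(),
               mismatch_positions = character(),
               site_observed = character(), guide_name = character(),
               stringsAsFactors = FALSE)
}

# Naive sliding-window Hamming scan, vectorized over windows. Independent
# of the compiled seed-and-verify path; also used by the synthetic-genome
# generator for rejection checks.
scan_seq_naive <- function(text, pat, budget) {
    n <- nchar(text); L <- nchar(pat)
    nw <- n - L + 1L
    if (nw <= 0L)
        return(list(start = integer(), mismatch_count = integer(),
                    mismatch_offsets = list(), skipped_windows = 0L))
    tx <- utf8ToInt(text); px <- utf8ToInt(pat)
    bad <- !(tx %in% utf8ToInt("A") |
             tx %in% utf8ToInt("C") |
             tx %in% utf8ToInt("G") |
             tx %in% utf8ToInt("T"))
    cb <- c(0L, cumsum(bad))
    badw <- (cb[(1:nw) + L] - cb[1:nw]) > 0L
    mm <- integer(nw)
    for (j in seq_len(L)) mm <- mm + (tx[j:(j + nw - 1L)] != px[j])
    keep <- which(!badw & mm <= budget)
    offs <- lapply(keep, function(w) {
        which(tx[w:(w + L - 1L)] != px)
    })
    list(start = keep - 1L, mismatch_count = mm[keep],
         mismatch_offsets = offs, skipped_windows = sum(badw))
}

#' Scan sequences for guide binding sites within a mismatch budget
#'
#' Enumerates every window whose Hamming distance to the guide's target
#' site is at most `budget` (no indels, strict base identity in DNA space;
#' G:U wobble is therefore a mismatch). On the minus strand the match is
#' against the site's reverse complement, reported in forward-strand
#' coordinates. Windows containing ambiguous bases (N) are skipped and
#' tallied, never reported.
#'
#' The default method anchors candidate windows by pigeonhole seeding
#' (budget k implies k+1 segments, one of which must match exactly) and
#' verifies them fully; `method = "naive"` runs an independent vectorized
#' sliding-window comparison. Both return the identical hit set.
#'
#' @param sequences A `DNAStringSet`, a named character vector, or a FASTA
#'   path (genome or transcriptome).
#' @param guide A [guide_strand()], nucleotide string, or
#'   [make_target_site()] result.
#' @param budget Maximum mismatches, 0-3.
#' @param strands `"both"` (genome scans) or `"sense"` (transcriptome scans,
#'   where the guide binds the mRNA and only the plus strand is meaningful).
#' @param method `"seed"` (compiled, default) or `"naive"`.
#' @return Data frame of hits with columns `sequence_id`, `strand`,
#'   `start`/`end` (0-based half-open, forward strand), `mismatch_count`,
#'   `mismatch_positions` (comma-separated 1-based guide coordinates),
#'   `site_observed` (forward-strand window) and `guide_name`; attribute
#'   `skipped_windows` carries the ambiguous-window tally.
#' @export
scan_offtargets <- function(sequences, guide, budget = 3L,
                            strands = c("both", "sense"),
                            method = c("seed", "naive")) {
    strands <- match.arg(strands)
    method <- match.arg(method)
    budget <- as.integer(budget)
    if (is.na(budget) || budget < 0L || budget > 3L)
        stop("budget must be between 0 and 3")
    seqs <- as_dna_stringset(sequences)
    if (length(seqs) == 0) stop("no sequences to scan")
    site <- if (inherits(guide, "target_site")) guide else make_target_site(guide)
    pat_plus <- site$site_sequence            # site on the forward strand
    pat_minus <- revcomp_dna(pat_plus)        # guide as DNA: minus-strand site
    L <- nchar(pat_plus)
    scan1 <- if (method == "seed") {
        function(text, pat) cpp_scan_hamming(text, pat, budget)
    } else {
        function(text, pat) scan_seq_naive(text, pat, budget)
    }
    out <- list()
    skipped <- 0L
    for (i in seq_along(seqs)) {
        text <- as.character(seqs[[i]])
        id <- names(seqs)[i]
        plus <- scan1(text, pat_plus)
        skipped <- skipped + plus$skipped_windows
        if (length(plus$start)) {
            # site index j maps to guide position L + 1 - j
            gp <- lapply(plus$mismatch_offsets,
                         function(o) sort(L + 1L - o))
            out[[length(out) + 1L]] <- data.frame(
                sequence_id = id, strand = "+",
                start = plus$start, end = plus$start + L,
                mismatch_count = plus$mismatch_count,
                mismatch_positions = vapply(gp, paste, "", collapse = ","),
                site_observed = substring(text, plus$start + 1L,
                                          plus$start + L),
                guide_name = site$guide_name, stringsAsFactors = FALSE)
        }
        if (strands == "both") {
            minus <- scan1(text, pat_minus)
            if (length(minus$start)) {
                # forward index i on the guide-as-DNA pattern IS the guide
                # position (complementation preserves mismatches)
                out[[length(out) + 1L]] <- data.frame(
                    sequence_id = id, strand = "-",
                    start = minus$start, end = minus$start + L,
                    mismatch_count = minus$mismatch_count,
                    mismatch_positions = vapply(minus$mismatch_offsets,
                                                paste, "", collapse = ","),
                    site_observed = substring(text, minus$start + 1L,
                                              minus$start + L),
                    guide_name = site$guide_name, stringsAsFactors = FALSE)
            }
        }
    }
    hits <- if (length(out)) do.call(rbind, out) else empty_hits()
    hits <- hits[order(hits$sequence_id, hits$start, hits$strand), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    attr(hits, "skipped_windows") <- skipped
    attr(hits, "params") <- list(guide = site$guide_name, budget = budget,
                                 strands = strands, method = method)
    hits
}

#' Merge overlapping off-target windows into loci
#'
#' Windows on the same sequence and strand overlapping by at least 1 bp are
#' merged transitively into a locus (book-ended windows stay separate).
#'
#' @param hits Hit table from [scan_offtargets()].
#' @return Data frame with columns `sequence_id`, `strand`, `start`, `end`
#'   (0-based half-open union span), `n_windows`, `min_mismatch_count`,
#'   `guide_name`.
#' @export
merge_loci <- function(hits) {
    if (nrow(hits) == 0)
        return(data.frame(sequence_id = character(), strand = character(),
                          start = integer(), end = integer(),
                          n_windows = integer(),
                          min_mismatch_count = integer(),
                          guide_name = character(), stringsAsFactors = FALSE))
    key <- paste(hits$sequence_id, hits$strand, sep = "\r")
    out <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
        h <- hits[idx, , drop = FALSE]
        ir <- IRanges::IRanges(start = h$start + 1L, end = h$end)
        red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
        rev <- S4Vectors::mcols(red)$revmap
        data.frame(
            sequence_id = h$sequence_id[1], strand = h$strand[1],
            start = IRanges::start(red) - 1L, end = IRanges::end(red),
            n_windows = lengths(rev),
            min_mismatch_count = vapply(rev, function(j)
                min(h$mismatch_count[j]), 0L),
            guide_name = h$guide_name[1], stringsAsFactors = FALSE)
    })
    loci <- do.call(rbind, out)
    loci <- loci[order(loci$sequence_id, loci$start, loci$strand), ,
                 drop = FALSE]
    rownames(loci) <- NULL
    loci
}

#' Annotate loci with genomic region types
#'
#' Each locus is labelled with every region type it overlaps by at least
#' 1 bp (strand-agnostic, since a site on either strand can fall in an
#' annotated transcript region); loci overlapping nothing are labelled
#' `intergenic`.
#'
#' @param loci Locus table from [merge_loci()].
#' @param regions Data frame with columns `sequence_id`, `start`, `end`
#'   (0-based half-open) and `type` (e.g. CDS, 5UTR, 3UTR, intron), or a
#'   `GRanges` with a `type` metadata column (see [read_regions()]).
#' @return `loci` with an added `region_labels` column (comma-separated).
#' @export
annotate_loci <- function(loci, regions) {
    regions <- as_region_df(regions)
    unknown <- setdiff(unique(regions$sequence_id),
                       unique(loci$sequence_id))
    if (length(unknown) > 0)
        warning("annotation references unknown sequence_id(s): ",
                paste(unknown, collapse = ", "))
    labels <- character(nrow(loci))
    for (sid in unique(loci$sequence_id)) {
        li <- which(loci$sequence_id == sid)
        ri <- which(regions$sequence_id == sid)
        if (length(ri) == 0) { labels[li] <- "intergenic"; next }
        lr <- IRanges::IRanges(loci$start[li] + 1L, loci$end[li])
        rr <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
        ov <- IRanges::findOverlaps(lr, rr, minoverlap = 1L)
        for (k in seq_along(li)) {
            types <- regions$type[ri[S4Vectors::subjectHits(ov)[
                S4Vectors::queryHits(ov) == k]]]
            labels[li[k]] <- if (length(types) == 0) "intergenic"
                else paste(sort(unique(types)), collapse = ",")
        }
    }
    loci$region_labels <- labels
    loci
}

as_region_df <- function(regions) {
    if (is(regions, "GRanges")) {
        mc <- S4Vectors::mcols(regions)
        type <- if ("type" %in% names(mc)) as.character(mc$type)
            else if ("name" %in% names(mc)) as.character(mc$name)
            else stop("GRanges annotation needs a 'type' or 'name' column")
        regions <- data.frame(
            sequence_id = as.character(GenomeInfoDb_seqnames(regions)),
            start = BiocGenerics::start(regions) - 1L,
            end = BiocGenerics::end(regions),
            type = type, stringsAsFactors = FALSE)
    }
    regions <- as.data.frame(regions)
    stopifnot(all(c("sequence_id", "start", "end", "type") %in%
                      names(regions)))
    regions
}

# seqnames without importing GenomeInfoDb directly (it comes with the
# GenomicRanges stack when a GRanges is supplied)
GenomeInfoDb_seqnames <- function(x) {
    as.character(methods::slot(x, "seqnames"))
}

#' Read a region annotation from BED or GFF3
#'
#' Thin wrapper over `rtracklayer::import()`. For GFF3 the feature `type`
#' is mapped to the labels used by [annotate_loci()] (`five_prime_UTR` to
#' `5UTR`, `three_prime_UTR` to `3UTR`); for BED the `name` field is taken
#' as the region type.
#'
#' @param path BED or GFF3 file.
#' @return Data frame with `sequence_id`, `start` (0-based), `end`, `type`.
#' @export
read_regions <- function(path) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("read_regions() requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    mc <- S4Vectors::mcols(gr)
    type <- if ("type" %in% names(mc)) as.character(mc$type)
        else as.character(mc$name)
    map <- c(five_prime_UTR = "5UTR", three_prime_UTR = "3UTR")
    type <- ifelse(type %in% names(map), map[type], type)
    data.frame(sequence_id = as.character(GenomeInfoDb_seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               type = unname(type), stringsAsFactors = FALSE)
}

#' Summarize off-target counts per guide at exact mismatch levels
#'
#' Counts hits in exact-mismatch bins k = 0..budget. At `level = "window"`
#' every hit window is counted; at `"locus"` merged loci are binned by
#' their minimum mismatch count; at `"transcript"` each sequence is counted
#' once at the minimum mismatch count of any of its hits (the usual reading
#' of predicted off-target transcript tables).
#'
#' @param guides A [guide_strand()] or list of them.
#' @param database Sequences to scan (see [scan_offtargets()]).
#' @param budget Maximum mismatches, 0-3.
#' @param level `"transcript"`, `"window"` or `"locus"`.
#' @param strands Defaults to `"sense"` for transcript level and `"both"`
#'   otherwise.
#' @return Data frame with one row per guide: `guide_name`, `level`, and
#'   columns `k0`..`k3` (exact-mismatch counts; `NA` beyond the budget).
#' @export
summarize_offtargets <- function(guides, database, budget = 2L,
                                 level = c("transcript", "window", "locus"),
                                 strands = NULL) {
    level <- match.arg(level)
    if (inherits(guides, "guide_strand")) guides <- list(guides)
    if (is.null(strands))
        strands <- if (level == "transcript") "sense" else "both"
    seqs <- as_dna_stringset(database)
    rows <- lapply(guides, function(g) {
        hits <- if (length(seqs) == 0) empty_hits() else
            scan_offtargets(seqs, g, budget = budget, strands = strands)
        ks <- switch(level,
            window = hits$mismatch_count,
            locus = merge_loci(hits)$min_mismatch_count,
            transcript = if (nrow(hits) == 0) integer() else
                vapply(split(hits$mismatch_count, hits$sequence_id),
                       min, 0L))
        counts <- vapply(0:3, function(k)
            if (k > budget) NA_integer_ else sum(ks == k), NA_integer_)
        data.frame(guide_name = if (inherits(g, "guide_strand")) g$name
                       else "guide",
                   level = level, k0 = counts[1], k1 = counts[2],
                   k2 = counts[3], k3 = counts[4],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "budget") <- budget
    attr(out, "strands") <- strands
    out
}

#' Rank guides by their off-target summaries
#'
#' Ascending lexicographic order on the exact-mismatch counts (k = 0, then
#' 1, 2, 3); ties broken alphabetically by guide name. The guide with the
#' fewest perfectly complementary sites, then the fewest one-mismatch
#' sites, and so on, ranks first.
#'
#' @param summaries Summary table from [summarize_offtargets()]. All rows
#'   must be at the same level and budget.
#' @return The summary table reordered, with a `rank` column prepended.
#' @export
rank_guides <- function(summaries) {
    stopifnot(is.data.frame(summaries),
              all(c("guide_name", "level", "k0") %in% names(summaries)))
    if (length(unique(summaries$level)) > 1)
        stop("summaries mix levels; rank within one level")
    na_pat <- apply(is.na(summaries[c("k0", "k1", "k2", "k3")]), 1, paste,
                    collapse = "")
    if (length(unique(na_pat)) > 1)
        stop("summaries mix budgets; rank within one budget")
    key <- summaries[c("k0", "k1", "k2", "k3")]
    key[is.na(key)] <- 0L
    o <- order(key$k0, key$k1, key$k2, key$k3, summaries$guide_name)
    out <- summaries[o, , drop = FALSE]
    out <- cbind(rank = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
}

run_header <- function(what, params) {
    c(paste0("# cagmir ", what),
      paste0("# ", names(params), "=",
             vapply(params, function(p) paste(format(p), collapse = ","), "")))
}

#' Write off-target hits as BED6
#'
#' Name is `guide:mismatch_count`, score is the mismatch count; coordinates
#' are 0-based half-open. A `#` header records the scan parameters.
#'
#' @param hits Hit table from [scan_offtargets()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path) {
    params <- attr(hits, "params")
    if (is.null(params)) params <- list()
    lines <- run_header("offtarget hits (BED6)", params)
    if (nrow(hits) > 0)
        lines <- c(lines, paste(hits$sequence_id, hits$start, hits$end,
                                paste0(hits$guide_name, ":",
                                       hits$mismatch_count),
                                hits$mismatch_count, hits$strand,
                                sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Write a locus or summary table as TSV with a parameter header
#'
#' @param x Data frame (e.g. from [merge_loci()], [annotate_loci()] or
#'   [summarize_offtargets()]).
#' @param path Output path.
#' @param params Named list recorded as `# key=value` header lines.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(x, path, params = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(run_header("table", params), con)
    write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
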
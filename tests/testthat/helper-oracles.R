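# Independent brute-force oracles, deliberately implemented on a different
# code path than the package (character vectors and raw bytes rather than
# the compiled seed-and-verify scanner or the vectorized counter).

A2_SEQ <- "CUGCUGCAGCUGCUGCUGC"

# mismatch positions of an RNA sequence against the phased CUG-repeat
# complement, by direct character comparison
oracle_mismatch_positions <- function(seq_rna, frame = 0) {
    cu <- c("C", "U", "G")
    g <- strsplit(seq_rna, "")[[1]]
    ref <- cu[((seq_along(g) - 1 + frame) %% 3) + 1]
    which(g != ref)
}

oracle_revcomp <- function(dna) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(dna, "")[[1]]), collapse = ""))
}

# naive sliding-window Hamming scan over raw bytes; returns a data frame of
# (strand, start, mismatch_count) rows, skipping windows with non-ACGT
oracle_scan <- function(text, site, budget, strands = "both") {
    L <- nchar(site)
    tb <- charToRaw(text)
    acgt <- charToRaw("ACGT")
    one <- function(pat, strand) {
        pb <- charToRaw(pat)
        nw <- length(tb) - L + 1
        if (nw < 1) return(NULL)
        rows <- list()
        for (w in seq_len(nw)) {
            win <- tb[w:(w + L - 1)]
            if (any(!(win %in% acgt))) next
            mm <- sum(win != pb)
            if (mm <= budget)
                rows[[length(rows) + 1]] <-
                    data.frame(strand = strand, start = w - 1L,
                               mismatch_count = mm)
        }
        if (length(rows)) do.call(rbind, rows) else NULL
    }
    out <- one(site, "+")
    if (strands == "both")
        out <- rbind(out, one(oracle_revcomp(site), "-"))
    if (is.null(out))
        out <- data.frame(strand = character(), start = integer(),
                          mismatch_count = integer())
    out[order(out$start, out$strand), , drop = FALSE]
}

# transitive union of intervals overlapping by >= 1 bp (0-based half-open)
oracle_merge <- function(starts, ends) {
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    ms <- starts[1]; me <- ends[1]; out <- NULL
    for (i in seq_along(starts)[-1]) {
        if (starts[i] < me) me <- max(me, ends[i])
        else { out <- rbind(out, c(ms, me)); ms <- starts[i]; me <- ends[i] }
    }
    rbind(out, c(ms, me))
}

random_dna <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
          collapse = "")
}

hit_key <- function(h) {
    k <- paste(h$strand, h$start, h$mismatch_count, sep = ":")
    sort(k)
}
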
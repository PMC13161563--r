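#' Write or read a ground-truth table
#'
#' Every synthetic generator emits a truth table sufficient to score the
#' corresponding pipeline stage (planted coordinates and mismatch counts,
#' mixture proportions, co-significant gene sets) without re-derivation.
#' Truth tables are serialized as YAML.
#'
#' @param truth Truth list from a generator.
#' @param path Output path.
#' @return [write_truth()]: invisibly `path`; [read_truth()]: the list.
#' @export
write_truth <- function(truth, path) {
    yaml::write_yaml(truth_to_plain(truth), path)
    invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) yaml::read_yaml(path)

truth_to_plain <- function(x) {
    if (is.data.frame(x)) return(as.list(x))
    if (is.list(x)) return(lapply(x, truth_to_plain))
    x
}

# Per-element seeds derived once from the master seed, so regenerating a
# subset of sequences/blocks is stable.
derive_subseeds <- function(seed, n) {
    set.seed(seed)
    sample.int(.Machine$integer.max %/% 2L, n)
}

random_background <- function(len, base_composition) {
    paste(sample(names(base_composition), len, replace = TRUE,
                 prob = base_composition), collapse = "")
}

mutate_site <- function(site, k) {
    if (k == 0L) return(site)
    L <- nchar(site)
    pos <- sample.int(L, k)
    chars <- strsplit(site, "")[[1]]
    for (p in pos)
        chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    paste(chars, collapse = "")
}

#' Generate a synthetic genome with planted off-target sites and repeat tracts
#'
#' Background sequence is random with the given base composition. Each
#' planted instance is the target site with exactly the requested number of
#' mismatched positions (drawn uniformly without replacement, each base
#' changed to a different one), inserted on a random strand at positions
#' separated by at least one site length. Repeat tracts are inserted
#' verbatim. The background is rejection-checked with the naive scanning
#' oracle so that it contains no accidental window within `scan_budget`
#' mismatches of any planted site pattern, and the assembled sequence is
#' re-verified, making the emitted truth table exact.
#'
#' @param n_sequences Number of sequences.
#' @param seq_length Length of each sequence (nt).
#' @param base_composition Named probabilities over A, C, G, T.
#' @param planted Data frame with columns `site` (DNA site sequence, e.g.
#'   from [make_target_site()]), `n_mismatches` (0-3) and `count`.
#' @param repeat_tracts Data frame with columns `unit`, `n_units`, `count`.
#' @param scan_budget Budget against which the background must be clean.
#' @param seed Mandatory RNG seed.
#' @param max_retries Per-sequence regeneration attempts before failing
#'   (composition too repeat-like).
#' @param fasta,truth_path Optional output paths (FASTA / YAML truth).
#' @return List with `sequences` (`DNAStringSet`) and `truth` (list with
#'   `planted_sites` and `tracts` data frames, seed and parameters).
#' @export
make_genome <- function(n_sequences = 10L, seq_length = 50000L,
                        base_composition = c(A = 0.3, C = 0.2, G = 0.2,
                                             T = 0.3),
                        planted = NULL, repeat_tracts = NULL,
                        scan_budget = 3L, seed, max_retries = 25L,
                        fasta = NULL, truth_path = NULL) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(setequal(names(base_composition), DNA_BASES))
    elements <- list()
    if (!is.null(planted)) {
        planted <- as.data.frame(planted)
        stopifnot(all(c("site", "n_mismatches", "count") %in% names(planted)))
        for (i in seq_len(nrow(planted))) {
            site <- normalize_seq(planted$site[i], "dna")
            for (j in seq_len(planted$count[i]))
                elements[[length(elements) + 1L]] <-
                    list(kind = "site", site = site,
                         k = as.integer(planted$n_mismatches[i]))
        }
    }
    if (!is.null(repeat_tracts)) {
        repeat_tracts <- as.data.frame(repeat_tracts)
        stopifnot(all(c("unit", "n_units", "count") %in% names(repeat_tracts)))
        for (i in seq_len(nrow(repeat_tracts))) {
            tr <- repeat_target(repeat_tracts$n_units[i],
                                repeat_tracts$unit[i])
            for (j in seq_len(repeat_tracts$count[i]))
                elements[[length(elements) + 1L]] <-
                    list(kind = "tract",
                         seq = repeat_sequence(tr, "dna"),
                         unit = tr$unit, n_units = tr$n_units)
        }
    }
    sites <- unique(vapply(Filter(function(e) e$kind == "site", elements),
                           `[[`, "", "site"))
    subseeds <- derive_subseeds(seed, n_sequences + 1L)
    set.seed(subseeds[n_sequences + 1L])
    elem_seq <- if (length(elements))
        sample.int(n_sequences, length(elements), replace = TRUE) else integer()

    seqs <- character(n_sequences)
    site_truth <- list()
    tract_truth <- list()
    for (i in seq_len(n_sequences)) {
        mine <- which(elem_seq == i)
        ok <- FALSE
        for (try in seq_len(max_retries)) {
            set.seed(subseeds[i] + try - 1L)
            bg <- random_background(seq_length, base_composition)
            # background must be clean at the scan budget for every site
            clean <- all(vapply(sites, function(s) {
                length(scan_seq_naive(bg, s, scan_budget)$start) == 0L &&
                length(scan_seq_naive(bg, revcomp_dna(s),
                                      scan_budget)$start) == 0L
            }, TRUE))
            if (!clean) next
            res <- place_elements(bg, elements[mine], scan_budget, sites)
            if (is.null(res)) next
            seqs[i] <- res$seq
            if (nrow(res$sites)) {
                res$sites <- cbind(sequence_id = paste0("synth", i),
                                   res$sites)
                site_truth[[length(site_truth) + 1L]] <- res$sites
            }
            if (nrow(res$tracts)) {
                res$tracts <- cbind(sequence_id = paste0("synth", i),
                                    res$tracts)
                tract_truth[[length(tract_truth) + 1L]] <- res$tracts
            }
            ok <- TRUE
            break
        }
        if (!ok)
            stop("could not generate a clean sequence after ", max_retries,
                 " retries (composition too repeat-like for budget ",
                 scan_budget, ")")
    }
    names(seqs) <- paste0("synth", seq_len(n_sequences))
    sset <- Biostrings::DNAStringSet(seqs)
    truth <- list(
        stage = "genome", seed = seed, scan_budget = scan_budget,
        n_sequences = n_sequences, seq_length = seq_length,
        planted_sites = if (length(site_truth)) do.call(rbind, site_truth)
            else data.frame(),
        tracts = if (length(tract_truth)) do.call(rbind, tract_truth)
            else data.frame())
    if (!is.null(fasta)) Biostrings::writeXStringSet(sset, fasta)
    if (!is.null(truth_path)) write_truth(truth, truth_path)
    list(sequences = sset, truth = truth)
}

# Insert elements into a background at well-separated positions and verify
# with the naive oracle that the only in-budget windows are the planted
# sites (at their stated distance) or windows overlapping a repeat tract.
place_elements <- function(bg, elems, scan_budget, sites) {
    n <- nchar(bg)
    s_rows <- list(); t_rows <- list()
    if (length(elems)) {
        lens <- vapply(elems, function(e)
            nchar(if (e$kind == "site") e$site else e$seq), 0L)
        margin <- max(lens) + 25L
        need <- sum(lens + margin)
        if (need > n - 2L * margin) stop("planted elements do not fit")
        starts <- sort(sample.int(n - max(lens) - margin, length(elems)))
        if (length(starts) > 1 &&
            any(diff(starts) < lens[-length(lens)] + margin)) return(NULL)
        for (j in seq_along(elems)) {
            e <- elems[[j]]
            at <- starts[j]                     # 0-based insert position
            if (e$kind == "site") {
                inst <- mutate_site(e$site, e$k)
                strand <- sample(c("+", "-"), 1)
                fwd <- if (strand == "+") inst else revcomp_dna(inst)
                substr(bg, at + 1L, at + nchar(fwd)) <- fwd
                s_rows[[length(s_rows) + 1L]] <- data.frame(
                    strand = strand, start = at, end = at + nchar(fwd),
                    n_mismatches = e$k, site = e$site,
                    stringsAsFactors = FALSE)
            } else {
                substr(bg, at + 1L, at + nchar(e$seq)) <- e$seq
                t_rows[[length(t_rows) + 1L]] <- data.frame(
                    start = at, end = at + nchar(e$seq), unit = e$unit,
                    n_units = e$n_units, stringsAsFactors = FALSE)
            }
        }
    }
    sdf <- if (length(s_rows)) do.call(rbind, s_rows) else
        data.frame(strand = character(), start = integer(), end = integer(),
                   n_mismatches = integer(), site = character())
    tdf <- if (length(t_rows)) do.call(rbind, t_rows) else
        data.frame(start = integer(), end = integer(), unit = character(),
                   n_units = integer())
    # full verification: every in-budget window must overlap a planted
    # element (a planted site instance at its stated distance, a shifted
    # window over a repeat-like planted site, or a repeat tract); nothing
    # may hit clean background
    for (s in sites) {
        for (strand in c("+", "-")) {
            pat <- if (strand == "+") s else revcomp_dna(s)
            sc <- scan_seq_naive(bg, pat, scan_budget)
            for (h in seq_along(sc$start)) {
                w0 <- sc$start[h]; w1 <- w0 + nchar(s)
                over_site <- nrow(sdf) > 0 && any(sdf$start < w1 &
                                                      w0 < sdf$end)
                over_tract <- nrow(tdf) > 0 && any(tdf$start < w1 &
                                                       w0 < tdf$end)
                if (!over_site && !over_tract) return(NULL)
            }
        }
    }
    list(seq = bg, sites = sdf, tracts = tdf)
}

#' Default small-RNA read mixture for a hairpin
#'
#' Models the processing-product composition of the 13A hairpin: two
#' dominant guide 5'-start variants (the +1-shifted variant at 35.9% and
#' the canonical start at 32.4%), other guide starts pooled (17.2%), and
#' the passenger strand (14.5%), so the guide arm totals 85.5% of assigned
#' reads. 3' heterogeneity is modelled by templated extension into the
#' hairpin (lengths 19-23 nt) plus non-templated tails.
#'
#' @param hairpin A [hairpin_annotation()].
#' @param depth Library depth (reads).
#' @param tail_rate Probability that a read carries a non-templated 3'
#'   tail of 1-2 nt.
#' @param ext_probs Probabilities of 0..4 nt templated 3' extension beyond
#'   the variant's base length.
#' @param endogenous List with `n_species`, `meanlog`, `sdlog`: a
#'   log-normal count law for the endogenous mature miRNA background.
#' @return Mixture specification list (`variants` data frame with
#'   `name`, `arm`, `start_offset`, `length`, `sequence`, `proportion`,
#'   plus the noise/depth fields).
#' @export
default_mixture <- function(hairpin, depth = 1e5, tail_rate = 0.15,
                            ext_probs = c(`0` = 0.55, `1` = 0.20, `2` = 0.12,
                                          `3` = 0.08, `4` = 0.05),
                            endogenous = list(n_species = 150, meanlog = 8,
                                              sdlog = 1.5)) {
    gs <- hairpin$guide_arm[1]
    gl <- hairpin$guide_arm[2] - gs
    ps <- hairpin$passenger_arm[1]
    pl <- hairpin$passenger_arm[2] - ps
    v <- data.frame(
        name = c("guide_plus1", "guide_canonical", "guide_other",
                 "passenger"),
        arm = c("guide", "guide", "guide", "passenger"),
        start_offset = c(gs - 1L, gs, gs + 1L, ps),
        length = c(gl + 1L, gl, gl - 1L, pl),
        proportion = c(0.359, 0.324, 0.172, 0.145),
        stringsAsFactors = FALSE)
    v$sequence <- substring(hairpin$sequence, v$start_offset + 1L,
                            v$start_offset + v$length)
    list(variants = v, depth = depth, tail_rate = tail_rate,
         ext_probs = ext_probs, endogenous = endogenous)
}

#' Generate a synthetic small-RNA library from a hairpin
#'
#' Draws reads multinomially at the stated depth from the mixture's
#' variants, adds templated 3' extensions and non-templated tails at the
#' stated rates (the first tail base is chosen to differ from the next
#' hairpin base so tails stay non-templated), and simulates an endogenous
#' mature miRNA count table from the mixture's log-normal law. Constant
#' quality is emitted in FASTQ output.
#'
#' @param hairpin A [hairpin_annotation()].
#' @param mixture Mixture specification (see [default_mixture()]).
#' @param seed Mandatory RNG seed.
#' @param fastq,truth_path Optional output paths.
#' @return List with `reads` (character vector), `endogenous` (named count
#'   vector) and `truth` (proportions, depth, counts, rates, seed; the
#'   `low_depth` flag is set for depths under 1000, where recovered
#'   fractions carry wide sampling error).
#' @export
make_reads <- function(hairpin, mixture = default_mixture(hairpin), seed,
                       fastq = NULL, truth_path = NULL) {
    if (missing(seed)) stop("seed is mandatory")
    v <- mixture$variants
    stopifnot(abs(sum(v$proportion) - 1) < 1e-8, mixture$depth >= 1)
    H <- nchar(hairpin$sequence)
    for (s in v$sequence)
        if (!grepl(s, hairpin$sequence, fixed = TRUE))
            stop("variant sequence absent from hairpin: ", s)
    subseeds <- derive_subseeds(seed, nrow(v) + 2L)
    set.seed(subseeds[nrow(v) + 1L])
    counts <- as.integer(rmultinom(1, mixture$depth, v$proportion))
    reads <- vector("list", nrow(v))
    for (i in seq_len(nrow(v))) {
        set.seed(subseeds[i])
        nn <- counts[i]
        if (nn == 0L) { reads[[i]] <- character(); next }
        ext <- sample(as.integer(names(mixture$ext_probs)), nn,
                      replace = TRUE, prob = mixture$ext_probs)
        endpos <- pmin(v$start_offset[i] + v$length[i] + ext, H)
        r <- substring(hairpin$sequence, v$start_offset[i] + 1L, endpos)
        tail_n <- ifelse(runif(nn) < mixture$tail_rate,
                         sample(1:2, nn, replace = TRUE), 0L)
        has_tail <- which(tail_n > 0L)
        for (j in has_tail) {
            nxt <- if (endpos[j] < H)
                substr(hairpin$sequence, endpos[j] + 1L, endpos[j] + 1L)
                else ""
            t1 <- sample(setdiff(DNA_BASES, nxt), 1)
            t2 <- if (tail_n[j] == 2L) sample(DNA_BASES, 1) else ""
            r[j] <- paste0(r[j], t1, t2)
        }
        reads[[i]] <- r
    }
    reads <- unlist(reads)
    set.seed(subseeds[nrow(v) + 2L])
    reads <- sample(reads)
    endo <- NULL
    if (!is.null(mixture$endogenous)) {
        e <- mixture$endogenous
        endo <- setNames(pmax(1, round(rlnorm(e$n_species, e$meanlog,
                                              e$sdlog))),
                         sprintf("miR-%03d", seq_len(e$n_species)))
    }
    truth <- list(stage = "reads", seed = seed, depth = mixture$depth,
                  hairpin = hairpin$name,
                  variants = cbind(v[c("name", "arm", "start_offset",
                                       "length", "proportion")],
                                   count = counts),
                  tail_rate = mixture$tail_rate,
                  ext_probs = as.list(mixture$ext_probs),
                  low_depth = mixture$depth < 1000)
    if (!is.null(fastq)) {
        ss <- Biostrings::DNAStringSet(reads)
        names(ss) <- sprintf("read%06d", seq_along(reads))
        quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
            strrep("I", n), ""))
        Biostrings::writeXStringSet(ss, fastq, format = "fastq",
                                    qualities = quals)
    }
    if (!is.null(truth_path)) write_truth(truth, truth_path)
    list(reads = reads, endogenous = endo, truth = truth)
}

#' Generate paired differential-expression tables with planted concordance
#'
#' Emulates a treated-vs-reference and an untreated-vs-reference DE table:
#' a planted set of co-significant genes receives paired log2 fold changes
#' drawn from a bivariate normal law with correlation `target_r` and
#' sub-alpha adjusted p-values; remaining genes are significant in at most
#' one table (never both) or in neither, so the shared significant set is
#' exactly the planted one.
#'
#' @param n_genes Total genes.
#' @param n_co_significant Planted co-significant genes.
#' @param target_r Target Pearson correlation of the planted effects in
#'   `[-1, 1]`.
#' @param effect_sd Standard deviation of the planted log2 fold changes.
#' @param alpha Significance threshold used for planting.
#' @param frac_single Fraction of the remaining genes significant in
#'   exactly one table (split evenly between the two).
#' @param seed Mandatory RNG seed.
#' @param prefix Optional output prefix; writes `<prefix>_treated.tsv`,
#'   `<prefix>_untreated.tsv` and `<prefix>_truth.yaml`.
#' @return List with `treated`, `untreated` (data frames with DESeq2-style
#'   columns `gene_id`, `log2FoldChange`, `pvalue`, `padj`) and `truth`.
#' @export
make_de_tables <- function(n_genes = 2000L, n_co_significant = 111L,
                           target_r = -0.81, effect_sd = 1, alpha = 0.05,
                           frac_single = 0.15, seed, prefix = NULL) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(abs(target_r) <= 1, n_co_significant <= n_genes)
    set.seed(seed)
    ids <- sprintf("gene%05d", seq_len(n_genes))
    co <- sort(sample.int(n_genes, n_co_significant))
    rest <- setdiff(seq_len(n_genes), co)
    cat1 <- sample(c("sigA", "sigB", "none"), length(rest), replace = TRUE,
                   prob = c(frac_single / 2, frac_single / 2,
                            1 - frac_single))
    lfc_a <- rnorm(n_genes, 0, 0.1 * effect_sd)
    lfc_b <- rnorm(n_genes, 0, 0.1 * effect_sd)
    # planted bivariate effects with correlation target_r
    x <- rnorm(n_co_significant, 0, effect_sd)
    y <- target_r * x +
        sqrt(max(0, 1 - target_r^2)) * rnorm(n_co_significant, 0, effect_sd)
    lfc_a[co] <- x
    lfc_b[co] <- y
    lfc_a[rest[cat1 == "sigA"]] <- rnorm(sum(cat1 == "sigA"), 0, effect_sd)
    lfc_b[rest[cat1 == "sigB"]] <- rnorm(sum(cat1 == "sigB"), 0, effect_sd)
    sig_p <- function(n) runif(n, 1e-8, 0.95 * alpha)
    ns_p <- function(n) runif(n, 1.0001 * alpha, 1)
    padj_a <- padj_b <- numeric(n_genes)
    padj_a[co] <- sig_p(n_co_significant)
    padj_b[co] <- sig_p(n_co_significant)
    padj_a[rest] <- ifelse(cat1 == "sigA", sig_p(length(rest)),
                           ns_p(length(rest)))
    padj_b[rest] <- ifelse(cat1 == "sigB", sig_p(length(rest)),
                           ns_p(length(rest)))
    pval_a <- padj_a * runif(n_genes, 0.05, 1)
    pval_b <- padj_b * runif(n_genes, 0.05, 1)
    mk <- function(l, p, pa) data.frame(gene_id = ids, log2FoldChange = l,
                                        pvalue = p, padj = pa,
                                        stringsAsFactors = FALSE)
    treated <- mk(lfc_a, pval_a, padj_a)
    untreated <- mk(lfc_b, pval_b, padj_b)
    truth <- list(stage = "de_tables", seed = seed, n_genes = n_genes,
                  n_co_significant = n_co_significant, target_r = target_r,
                  alpha = alpha, co_significant = ids[co])
    if (!is.null(prefix)) {
        write.table(treated, paste0(prefix, "_treated.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(untreated, paste0(prefix, "_untreated.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write_truth(truth, paste0(prefix, "_truth.yaml"))
    }
    list(treated = treated, untreated = untreated, truth = truth)
}
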
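#' Annotate an amiRNA hairpin
#'
#' Describes the pri-miRNA-scaffold hairpin a small-RNA library is matched
#' against: the full hairpin sequence (5' to 3', stored as DNA, i.e. in
#' read space) and the intervals of the guide and passenger arms.
#'
#' @param name Hairpin label.
#' @param sequence Hairpin sequence 5' to 3' (RNA or DNA accepted).
#' @param guide_arm,passenger_arm Integer length-2 vectors `c(start, end)`,
#'   0-based half-open intervals on the hairpin; must not overlap.
#' @param start_slack Tolerance (nt) around an arm's 5' end when assigning
#'   read start offsets to arms (default 5).
#' @return Object of class `"hairpin_annotation"`.
#' @export
hairpin_annotation <- function(name, sequence, guide_arm, passenger_arm,
                               start_slack = 5L) {
    sequence <- normalize_seq(sequence, "dna")
    H <- nchar(sequence)
    chk <- function(arm, lab) {
        arm <- as.integer(arm)
        if (length(arm) != 2L || arm[1] < 0L || arm[2] > H ||
            arm[1] >= arm[2])
            stop(lab, " must be a 0-based half-open interval within the hairpin")
        arm
    }
    guide_arm <- chk(guide_arm, "guide_arm")
    passenger_arm <- chk(passenger_arm, "passenger_arm")
    if (max(guide_arm[1], passenger_arm[1]) <
        min(guide_arm[2], passenger_arm[2]))
        stop("guide and passenger arms overlap")
    structure(list(name = name, sequence = sequence,
                   guide_arm = guide_arm, passenger_arm = passenger_arm,
                   start_slack = as.integer(start_slack),
                   guide_is_5p = guide_arm[1] < passenger_arm[1]),
              class = "hairpin_annotation")
}

#' @export
print.hairpin_annotation <- function(x, ...) {
    cat("hairpin_annotation ", x$name, " (", nchar(x$sequence), " nt)\n",
        "  guide arm (", if (x$guide_is_5p) "5p" else "3p", "): [",
        x$guide_arm[1], ",", x$guide_arm[2], ")  passenger arm: [",
        x$passenger_arm[1], ",", x$passenger_arm[2], ")  start slack ",
        x$start_slack, " nt\n", sep = "")
    invisible(x)
}

#' Synthetic amiR-13A-style hairpin
#'
#' A synthetic stand-in for an amiRNA hairpin carrying the 13A guide on its
#' 5' arm and the complementary passenger on the 3' arm, with arbitrary
#' non-repeat flanks and loop. The base immediately 5' of the guide arm is
#' a G that pairs perfectly in the repeat register, so the +1 5'-shifted
#' isomiR carries its design mismatches at positions 9 and 14 (shifted by
#' +1 from the canonical 8 and 13).
#'
#' @return A [hairpin_annotation()].
#' @export
amir13a_hairpin <- function() {
    flank5 <- "ACGGTATG"                       # ends in the pairing G
    guide <- "CTGCTGCAGCTGATGCTGC"             # 13A guide, read space
    loop <- "TCACATTCA"
    passenger <- revcomp_dna(guide)
    flank3 <- "CCTATGAC"
    seq <- paste0(flank5, guide, loop, passenger, flank3)
    gs <- nchar(flank5)
    ps <- gs + nchar(guide) + nchar(loop)
    hairpin_annotation("amiR-13A-synthetic", seq,
                       guide_arm = c(gs, gs + nchar(guide)),
                       passenger_arm = c(ps, ps + nchar(passenger)))
}

#' Read or write a hairpin annotation as YAML
#'
#' @param path YAML file with fields `name`, `sequence`, `guide_arm`,
#'   `passenger_arm`, `start_slack`.
#' @return [read_hairpin_config()]: a [hairpin_annotation()];
#'   [write_hairpin_config()]: invisibly, `path`.
#' @export
read_hairpin_config <- function(path) {
    y <- yaml::read_yaml(path)
    hairpin_annotation(y$name, y$sequence, unlist(y$guide_arm),
                       unlist(y$passenger_arm),
                       start_slack = if (is.null(y$start_slack)) 5L
                           else y$start_slack)
}

#' @rdname read_hairpin_config
#' @param hairpin A [hairpin_annotation()].
#' @export
write_hairpin_config <- function(hairpin, path) {
    yaml::write_yaml(list(name = hairpin$name, sequence = hairpin$sequence,
                          guide_arm = hairpin$guide_arm,
                          passenger_arm = hairpin$passenger_arm,
                          start_slack = hairpin$start_slack), path)
    invisible(path)
}

# Longest exact match of a read prefix at every hairpin offset; returns the
# best offset under the assignment policy. Ties on matched length are broken
# by the leftmost offset falling within an annotated arm (expanded by the
# start slack), then the leftmost offset overall; ties are tallied.
match_read_to_hairpin <- function(read, hairpin) {
    H <- nchar(hairpin$sequence)
    n <- nchar(read)
    hx <- utf8ToInt(hairpin$sequence)
    rx <- utf8ToInt(read)
    best_len <- 0L
    best_offs <- integer()
    for (o in 0:(H - 1L)) {
        m <- min(n, H - o)
        j <- 0L
        while (j < m && hx[o + j + 1L] == rx[j + 1L]) j <- j + 1L
        if (j > best_len) { best_len <- j; best_offs <- o }
        else if (j == best_len && j > 0L) best_offs <- c(best_offs, o)
    }
    list(len = best_len, offsets = best_offs)
}

arm_of_offset <- function(offset, hairpin) {
    s <- hairpin$start_slack
    within <- function(arm) offset >= arm[1] - s & offset <= arm[2] - 1L + s
    if (within(hairpin$guide_arm)) "guide"
    else if (within(hairpin$passenger_arm)) "passenger"
    else "unassigned"
}

#' Assign a small-RNA read to a hairpin arm and 5' start offset
#'
#' The longest prefix of the read matching the hairpin exactly locates the
#' read; up to `max_nontemplated_3p` trailing unmatched nucleotides
#' (non-templated 3' additions) are tolerated. The 5' match position is the
#' start offset; the read is assigned to the arm whose interval, expanded
#' by the hairpin's start slack, contains that offset. Reads failing any
#' condition are returned as `unassigned`, never dropped. When several
#' offsets tie for the longest match (the repeat-rich insert makes this
#' possible), the leftmost offset within an annotated arm wins, then the
#' leftmost overall, and the ambiguity is flagged.
#'
#' @param read Read sequence (adapter-trimmed; RNA or DNA).
#' @param hairpin A [hairpin_annotation()].
#' @param max_nontemplated_3p Maximum tolerated non-templated 3' tail
#'   (default 2 nt).
#' @param length_bounds Acceptable read-length range (default 15-30 nt).
#' @return List with `arm` (`"guide"`, `"passenger"` or `"unassigned"`),
#'   `start_offset` (0-based hairpin position, `NA` if unassigned),
#'   `templated_length` and `ambiguous`.
#' @export
assign_read <- function(read, hairpin, max_nontemplated_3p = 2L,
                        length_bounds = c(15L, 30L)) {
    read <- normalize_seq(read, "dna")
    n <- nchar(read)
    una <- list(arm = "unassigned", start_offset = NA_integer_,
                templated_length = NA_integer_, ambiguous = FALSE)
    if (n < length_bounds[1] || n > length_bounds[2]) return(una)
    m <- match_read_to_hairpin(read, hairpin)
    if (m$len == 0L || n - m$len > max_nontemplated_3p) return(una)
    offs <- m$offsets
    ambiguous <- length(offs) > 1L
    arms <- vapply(offs, arm_of_offset, "", hairpin = hairpin)
    in_arm <- offs[arms != "unassigned"]
    off <- if (length(in_arm) > 0) min(in_arm) else min(offs)
    arm <- arm_of_offset(off, hairpin)
    if (arm == "unassigned")
        return(list(arm = "unassigned", start_offset = off,
                    templated_length = m$len, ambiguous = ambiguous))
    list(arm = arm, start_offset = off, templated_length = m$len,
         ambiguous = ambiguous)
}

# Vectorized assignment over a collapsed (sequence, count) table.
assign_read_table <- function(reads, hairpin, max_nontemplated_3p = 2L,
                              length_bounds = c(15L, 30L)) {
    stopifnot(is.data.frame(reads),
              all(c("sequence", "count") %in% names(reads)))
    res <- lapply(reads$sequence, assign_read, hairpin = hairpin,
                  max_nontemplated_3p = max_nontemplated_3p,
                  length_bounds = length_bounds)
    data.frame(sequence = reads$sequence, count = reads$count,
               arm = vapply(res, `[[`, "", "arm"),
               start_offset = vapply(res, `[[`, NA_integer_, "start_offset"),
               templated_length = vapply(res, `[[`, NA_integer_,
                                         "templated_length"),
               ambiguous = vapply(res, `[[`, NA, "ambiguous"),
               stringsAsFactors = FALSE)
}

#' Group assigned reads into 5'-start-site variants
#'
#' One group per (arm, start offset); groups below `min_fraction` percent
#' of assigned reads are pooled into a per-arm `other` group. Fractions are
#' computed over assigned reads. The representative sequence of a group is
#' its most abundant templated sequence (ties by the shorter, then
#' alphabetical).
#'
#' @param assignments Assignment table from [assign_read_table()] (or built
#'   internally by [process_smallrna()]).
#' @param hairpin The [hairpin_annotation()] reads were assigned against.
#' @param min_fraction Pooling threshold in percent (default 0.5).
#' @return Data frame with columns `arm`, `start_offset` (`NA` for pooled
#'   groups), `representative_sequence`, `read_count`,
#'   `fraction_of_assigned`, `lengths` (list column of templated-length
#'   tables).
#' @export
group_variants <- function(assignments, hairpin, min_fraction = 0.5) {
    a <- assignments[assignments$arm != "unassigned", , drop = FALSE]
    n_assigned <- sum(a$count)
    if (n_assigned == 0L) stop("no assigned reads: empty or foreign library")
    a$templated_seq <- substring(hairpin$sequence, a$start_offset + 1L,
                                 a$start_offset + a$templated_length)
    key <- paste(a$arm, a$start_offset, sep = "\r")
    grp <- lapply(split(seq_len(nrow(a)), key), function(idx) {
        g <- a[idx, , drop = FALSE]
        byseq <- tapply(g$count, g$templated_seq, sum)
        byseq <- byseq[order(-byseq, nchar(names(byseq)), names(byseq))]
        lens <- tapply(g$count, g$templated_length, sum)
        data.frame(arm = g$arm[1], start_offset = g$start_offset[1],
                   representative_sequence = names(byseq)[1],
                   read_count = sum(g$count),
                   lengths = I(list(lens)), stringsAsFactors = FALSE)
    })
    groups <- do.call(rbind, grp)
    groups$fraction_of_assigned <- 100 * groups$read_count / n_assigned
    small <- groups$fraction_of_assigned < min_fraction
    if (any(small)) {
        pooled <- lapply(split(which(small), groups$arm[small]), function(i) {
            lens <- tapply(
                unlist(lapply(groups$lengths[i], as.vector)),
                unlist(lapply(groups$lengths[i], names)), sum)
            data.frame(arm = groups$arm[i[1]], start_offset = NA_integer_,
                       representative_sequence = NA_character_,
                       read_count = sum(groups$read_count[i]),
                       lengths = I(list(lens)),
                       fraction_of_assigned =
                           sum(groups$fraction_of_assigned[i]),
                       stringsAsFactors = FALSE)
        })
        groups <- rbind(groups[!small, , drop = FALSE],
                        do.call(rbind, pooled))
    }
    groups <- groups[order(match(groups$arm, c("guide", "passenger")),
                           is.na(groups$start_offset),
                           groups$start_offset), , drop = FALSE]
    rownames(groups) <- NULL
    attr(groups, "n_assigned") <- n_assigned
    groups
}

#' Strand bias of hairpin processing
#'
#' Percentage split of assigned reads between guide and passenger arms;
#' the two percentages sum to 100.
#'
#' @param groups Variant table from [group_variants()].
#' @return Named numeric vector `c(guide = , passenger = )`.
#' @export
strand_bias <- function(groups) {
    tot <- sum(groups$read_count)
    if (tot == 0) stop("no assigned reads")
    g <- sum(groups$read_count[groups$arm == "guide"])
    c(guide = 100 * g / tot, passenger = 100 * (tot - g) / tot)
}

#' Templated-length distribution of assigned reads
#'
#' @param groups Variant table from [group_variants()].
#' @return Named integer vector: counts by templated read length.
#' @export
length_distribution <- function(groups) {
    lens <- tapply(unlist(lapply(groups$lengths, as.vector)),
                   unlist(lapply(groups$lengths, names)), sum)
    lens <- lens[order(as.integer(names(lens)))]
    v <- as.integer(lens)
    names(v) <- names(lens)
    v
}

#' amiRNA abundance relative to the top-N endogenous miRNAs
#'
#' The amiRNA read count as a percentage of the summed counts of the N most
#' abundant endogenous mature miRNAs (the amiRNA itself must not be in the
#' endogenous table). With fewer than N species the sum runs over all of
#' them, with a warning.
#'
#' @param amirna_total Total amiRNA-derived read count.
#' @param endogenous Named numeric vector of endogenous mature miRNA counts.
#' @param n Number of top species to sum (default 50).
#' @return Percentage (scale 0-100).
#' @examples
#' top_n_fraction(71, setNames(rep(200, 50), paste0("miR", 1:50)))  # 0.71
#' @export
top_n_fraction <- function(amirna_total, endogenous, n = 50L) {
    if (length(endogenous) == 0) stop("endogenous miRNA table is empty")
    if (all(endogenous == 0)) stop("endogenous miRNA counts are all zero")
    if (length(endogenous) < n) {
        warning("fewer than ", n, " endogenous species; summing over all ",
                length(endogenous))
        n <- length(endogenous)
    }
    topsum <- sum(sort(endogenous, decreasing = TRUE)[seq_len(n)])
    100 * amirna_total / topsum
}

#' Annotate guide-arm variant groups with repeat-register mismatches
#'
#' Runs each guide-arm group's representative sequence through
#' [mismatch_profile()] at its best frame against the repeat target and
#' attaches the mismatch positions (1-based from the read 5' end). A group
#' whose 5' start is shifted +1 relative to the canonical guide has every
#' register mismatch shifted by +1.
#'
#' @param groups Variant table from [group_variants()].
#' @param target A [repeat_target()] (default 28 CAG units).
#' @return `groups` with added `register_mismatches` (comma-separated) and
#'   `register_frame` columns (`NA` for passenger and pooled groups).
#' @export
annotate_registers <- function(groups, target = repeat_target(28)) {
    reg <- rep(NA_character_, nrow(groups))
    frm <- rep(NA_integer_, nrow(groups))
    idx <- which(groups$arm == "guide" &
                     !is.na(groups$representative_sequence))
    for (i in idx) {
        s <- chartr("T", "U", groups$representative_sequence[i])
        profs <- lapply(0:2, function(f)
            mismatch_positions_chr(s, target$unit, f))
        f <- which.min(vapply(profs, length, 0L)) - 1L
        reg[i] <- paste(profs[[f + 1L]], collapse = ",")
        frm[i] <- f
    }
    groups$register_mismatches <- reg
    groups$register_frame <- frm
    groups
}

#' Read a small-RNA library
#'
#' Accepts FASTQ or FASTA (by extension, `.gz` allowed), a two-column
#' `sequence<TAB>count` collapsed table, a character vector of reads, or a
#' `DNAStringSet`. Reads are collapsed to a (sequence, count) table.
#'
#' @param x Input (path, character vector, or `DNAStringSet`).
#' @return Data frame with columns `sequence`, `count`.
#' @export
read_smallrna <- function(x) {
    if (is(x, "DNAStringSet")) x <- as.character(x)
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
        stem <- sub("\\.gz$", "", x)
        if (grepl("\\.(fastq|fq)$", stem, ignore.case = TRUE)) {
            x <- as.character(Biostrings::readDNAStringSet(x, format = "fastq"))
        } else if (grepl("\\.(fasta|fa|fna)$", stem, ignore.case = TRUE)) {
            x <- as.character(Biostrings::readDNAStringSet(x))
        } else {
            d <- read.delim(x, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
            if (ncol(d) < 2) stop("collapsed read table needs sequence<TAB>count")
            names(d)[1:2] <- c("sequence", "count")
            if (identical(tolower(d$sequence[1]), "sequence"))
                d <- d[-1, , drop = FALSE]
            d$count <- as.integer(d$count)
            d$sequence <- normalize_seq_vec(d$sequence)
            return(d[c("sequence", "count")])
        }
    }
    x <- normalize_seq_vec(x)
    tab <- table(x)
    data.frame(sequence = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
}

normalize_seq_vec <- function(x) toupper(chartr("uU", "TT", x))

#' Profile hairpin processing from a small-RNA library
#'
#' End-to-end small-RNA analysis: reads are assigned to hairpin arms and 5'
#' start offsets, grouped into isomiR variants, and summarized as strand
#' bias, variant fractions, templated-length distribution, repeat-register
#' mismatches, and (when endogenous counts are supplied) the amiRNA's
#' abundance relative to the top-N endogenous miRNAs.
#'
#' @param reads Input accepted by [read_smallrna()].
#' @param hairpin A [hairpin_annotation()].
#' @param endogenous Optional named vector of endogenous mature miRNA
#'   counts (excluding the amiRNA).
#' @param target A [repeat_target()] for register annotation.
#' @param min_fraction Variant pooling threshold, percent.
#' @param max_nontemplated_3p,length_bounds See [assign_read()].
#' @param top_n N for [top_n_fraction()].
#' @return Object of class `"processing_report"`: list with read tallies,
#'   `strand_bias`, `variant_table`, `length_histogram`,
#'   `top_n_fraction_percent`, `all_mirna_fraction_percent`, `n_ambiguous`
#'   and the run parameters.
#' @export
process_smallrna <- function(reads, hairpin, endogenous = NULL,
                             target = repeat_target(28), min_fraction = 0.5,
                             max_nontemplated_3p = 2L,
                             length_bounds = c(15L, 30L), top_n = 50L) {
    tab <- read_smallrna(reads)
    asg <- assign_read_table(tab, hairpin,
                             max_nontemplated_3p = max_nontemplated_3p,
                             length_bounds = length_bounds)
    n_total <- sum(asg$count)
    n_unassigned <- sum(asg$count[asg$arm == "unassigned"])
    groups <- group_variants(asg, hairpin, min_fraction = min_fraction)
    groups <- annotate_registers(groups, target)
    bias <- strand_bias(groups)
    hist <- length_distribution(groups)
    n_assigned <- n_total - n_unassigned
    topf <- allf <- NA_real_
    if (!is.null(endogenous)) {
        topf <- top_n_fraction(n_assigned, endogenous, n = top_n)
        allf <- 100 * n_assigned / sum(endogenous)
    }
    structure(list(
        hairpin = hairpin$name,
        n_reads_total = n_total, n_assigned = n_assigned,
        n_unassigned = n_unassigned,
        n_ambiguous = sum(asg$count[asg$ambiguous & asg$arm != "unassigned"]),
        strand_bias = bias, variant_table = groups,
        length_histogram = hist,
        top_n_fraction_percent = topf,
        all_mirna_fraction_percent = allf,
        params = list(min_fraction = min_fraction,
                      max_nontemplated_3p = max_nontemplated_3p,
                      length_bounds = length_bounds, top_n = top_n,
                      start_slack = hairpin$start_slack)),
        class = "processing_report")
}

#' @export
print.processing_report <- function(x, ...) {
    cat("processing_report for", x$hairpin, "\n")
    cat(sprintf("  reads: %d total, %d assigned, %d unassigned (%d ambiguous)\n",
                x$n_reads_total, x$n_assigned, x$n_unassigned, x$n_ambiguous))
    cat(sprintf("  strand bias: guide %.1f%% / passenger %.1f%%\n",
                x$strand_bias["guide"], x$strand_bias["passenger"]))
    vt <- x$variant_table
    for (i in seq_len(nrow(vt)))
        cat(sprintf("  %s +%s: %.1f%% (%d reads)%s\n", vt$arm[i],
                    ifelse(is.na(vt$start_offset[i]), "other",
                           vt$start_offset[i]),
                    vt$fraction_of_assigned[i], vt$read_count[i],
                    ifelse(is.na(vt$register_mismatches[i]), "",
                           paste0("  register mismatches {",
                                  vt$register_mismatches[i], "}"))))
    if (!is.na(x$top_n_fraction_percent))
        cat(sprintf("  amiRNA vs top-%d endogenous miRNAs: %.2f%%\n",
                    x$params$top_n, x$top_n_fraction_percent))
    invisible(x)
}

#' Write a processing report as TSV (variant table) and optional JSON
#'
#' @param report A [process_smallrna()] result.
#' @param tsv Output TSV path for the variant table.
#' @param json Optional JSON path for the full report.
#' @return Invisibly, `tsv`.
#' @export
write_processing_report <- function(report, tsv, json = NULL) {
    vt <- report$variant_table
    vt$lengths <- vapply(vt$lengths, function(l)
        paste(names(l), as.integer(l), sep = ":", collapse = ","), "")
    write_tsv_report(vt, tsv, params = c(
        list(hairpin = report$hairpin,
             strand_bias_guide_percent = report$strand_bias[["guide"]],
             n_reads_total = report$n_reads_total,
             n_assigned = report$n_assigned,
             n_unassigned = report$n_unassigned),
        report$params))
    if (!is.null(json)) {
        rep2 <- report
        rep2$variant_table <- vt
        rep2$length_histogram <- as.list(report$length_histogram)
        jsonlite::write_json(unclass(rep2), json, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE, force = TRUE)
    }
    invisible(tsv)
}
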
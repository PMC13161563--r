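#' Construct a guide strand
#'
#' A guide strand is a short RNA (19-23 nt, written 5' to 3') intended to
#' base-pair with a CAG-repeat tract in a transcript. Designed guides are
#' derived from the parental A2 sequence by single-base substitutions, and
#' the substitution history is carried alongside the sequence.
#'
#' @param name Guide label (e.g. `"A2"`, `"13A"`).
#' @param sequence Nucleotide string, 5' to 3'. `U` and `T` are accepted
#'   interchangeably; the guide is stored as RNA.
#' @param substitutions Optional data frame with columns `position`
#'   (1-based from the 5' end), `from`, `to`, recording edits relative to
#'   `parent`. Empty for a parental guide.
#' @param parent Optional parent [guide_strand()]. When given, applying
#'   `substitutions` to the parent must reproduce `sequence` exactly.
#' @return An object of class `"guide_strand"`: a list with elements
#'   `name`, `sequence` and `substitutions`.
#' @examples
#' a2 <- a2_guide()
#' g13a <- apply_substitution(a2, 13, "A")
#' g13a$sequence
#' @export
guide_strand <- function(name, sequence, substitutions = NULL, parent = NULL) {
    sequence <- normalize_seq(sequence, "rna")
    L <- nchar(sequence)
    if (L < 19 || L > 23)
        stop("guide length must be between 19 and 23 nt, got ", L)
    if (is.null(substitutions)) {
        substitutions <- data.frame(position = integer(), from = character(),
                                    to = character())
    } else {
        substitutions <- as.data.frame(substitutions)
        stopifnot(all(c("position", "from", "to") %in% names(substitutions)))
        substitutions$position <- as.integer(substitutions$position)
        if (any(substitutions$position < 1L | substitutions$position > L))
            stop("substitution position outside [1, ", L, "]")
    }
    if (!is.null(parent)) {
        s <- parent$sequence
        for (i in seq_len(nrow(substitutions))) {
            p <- substitutions$position[i]
            if (substr(s, p, p) != substitutions$from[i])
                stop("substitution record does not match parent base at ", p)
            substr(s, p, p) <- substitutions$to[i]
        }
        if (s != sequence)
            stop("applying substitutions to parent does not reproduce sequence")
    }
    structure(list(name = name, sequence = sequence,
                   substitutions = substitutions),
              class = "guide_strand")
}

#' @export
print.guide_strand <- function(x, ...) {
    cat("guide_strand ", x$name, ": 5'-", x$sequence, "-3' (",
        nchar(x$sequence), " nt)\n", sep = "")
    if (nrow(x$substitutions) > 0) {
        cat("  substitutions vs parent:",
            paste0(x$substitutions$position, x$substitutions$from, ">",
                   x$substitutions$to, collapse = ", "), "\n")
    }
    invisible(x)
}

as_guide_sequence <- function(guide) {
    if (inherits(guide, "guide_strand")) guide$sequence
    else normalize_seq(guide, "rna")
}

#' The parental A2 guide strand
#'
#' The 19-nt CUG-repeat-like guide 5'-CUGCUGCAGCUGCUGCUGC-3', carrying a
#' single repeat interruption at position 8 that forms an A:A mismatch with
#' a CAG-repeat target.
#'
#' @return A [guide_strand()].
#' @export
a2_guide <- function() guide_strand("A2", "CUGCUGCAGCUGCUGCUGC")

#' Substitute one base of a guide strand
#'
#' Produces a new guide differing from `parent` at exactly one position and
#' extends the substitution record. Guides are named by appending the edit
#' (e.g. position 13 C>A on A2 gives `"13A"`; a further 16 C>U gives
#' `"13A16U"`).
#'
#' @param parent A [guide_strand()].
#' @param position 1-based position from the 5' end.
#' @param new_base Replacement RNA base; must differ from the current base
#'   (an equal base signals a no-op design error).
#' @param name Optional name for the variant; derived from the parent name
#'   and the edit when `NULL`.
#' @return A [guide_strand()].
#' @export
apply_substitution <- function(parent, position, new_base, name = NULL) {
    stopifnot(inherits(parent, "guide_strand"))
    L <- nchar(parent$sequence)
    position <- as.integer(position)
    if (is.na(position) || position < 1L || position > L)
        stop("position out of range [1, ", L, "]")
    new_base <- normalize_seq(new_base, "rna")
    if (nchar(new_base) != 1L) stop("new_base must be a single base")
    old <- substr(parent$sequence, position, position)
    if (new_base == old)
        stop("new_base equals the current base at position ", position,
             " (no-op substitution)")
    s <- parent$sequence
    substr(s, position, position) <- new_base
    if (is.null(name)) {
        stem <- if (identical(parent$name, "A2")) "" else parent$name
        name <- paste0(stem, position, new_base)
    }
    # substitution records are cumulative relative to the root parent;
    # rebuild it by reverting the parent's own records
    root <- parent$sequence
    if (nrow(parent$substitutions) > 0)
        for (i in rev(seq_len(nrow(parent$substitutions))))
            substr(root, parent$substitutions$position[i],
                   parent$substitutions$position[i]) <-
                parent$substitutions$from[i]
    guide_strand(name, s,
                 substitutions = rbind(parent$substitutions,
                                       data.frame(position = position,
                                                  from = old, to = new_base)),
                 parent = guide_strand(paste0(parent$name, "_root"), root))
}

#' The designed guide-strand variants
#'
#' The A2 parent together with its published single-substitution variants
#' 9A (G>A), 10A (C>A), 11A (U>A), 13G (C>G) and 13A (C>A), and the
#' double-substitution variant 13G16U.
#'
#' @return Named list of [guide_strand()] objects.
#' @export
designed_guides <- function() {
    a2 <- a2_guide()
    g13g <- apply_substitution(a2, 13, "G")
    gs <- list(
        A2 = a2,
        `9A` = apply_substitution(a2, 9, "A"),
        `10A` = apply_substitution(a2, 10, "A"),
        `11A` = apply_substitution(a2, 11, "A"),
        `13G` = g13g,
        `13A` = apply_substitution(a2, 13, "A"),
        `13G16U` = apply_substitution(g13g, 16, "U")
    )
    gs
}

#' Construct a trinucleotide repeat target
#'
#' Represents a repeat tract in transcript sense, by default a pure CAG
#' repeat. Interruptions replace whole repeat units (as in the CAA-interrupted
#' tracts of some disease models).
#'
#' @param n_units Number of repeat units (>= 1).
#' @param unit Trinucleotide unit, default `"CAG"`.
#' @param interruptions Optional data frame with columns `unit_index`
#'   (1-based) and `replacement_unit`.
#' @return Object of class `"repeat_target"`.
#' @export
repeat_target <- function(n_units, unit = "CAG", interruptions = NULL) {
    unit <- normalize_seq(unit, "rna")
    if (nchar(unit) != 3L) stop("repeat unit must be exactly 3 nt")
    n_units <- as.integer(n_units)
    if (is.na(n_units) || n_units < 1L) stop("n_units must be >= 1")
    if (!is.null(interruptions)) {
        interruptions <- as.data.frame(interruptions)
        stopifnot(all(c("unit_index", "replacement_unit") %in%
                          names(interruptions)))
        if (any(interruptions$unit_index < 1 |
                interruptions$unit_index > n_units))
            stop("interruption unit_index out of range")
        interruptions$replacement_unit <-
            vapply(interruptions$replacement_unit, normalize_seq, "",
                   alphabet = "rna")
        if (any(nchar(interruptions$replacement_unit) != 3L))
            stop("replacement units must be 3 nt")
    }
    structure(list(unit = unit, n_units = n_units,
                   interruptions = interruptions),
              class = "repeat_target")
}

#' Expand a repeat target to its transcript-sense sequence
#'
#' @param target A [repeat_target()].
#' @param alphabet `"rna"` (default) or `"dna"`.
#' @return Character string of length `3 * n_units`.
#' @export
repeat_sequence <- function(target, alphabet = c("rna", "dna")) {
    alphabet <- match.arg(alphabet)
    stopifnot(inherits(target, "repeat_target"))
    units <- rep(target$unit, target$n_units)
    if (!is.null(target$interruptions))
        units[target$interruptions$unit_index] <-
            target$interruptions$replacement_unit
    normalize_seq(paste(units, collapse = ""), alphabet)
}

# The phased repeat-complement reference the guide is compared against:
# for unit CAG this is the (CUG) repeat, with frame 0 starting at C.
complement_reference <- function(unit, length, frame) {
    comp_unit <- chartr("T", "U",
                        revcomp_dna(normalize_seq(unit, "dna")))
    cu <- strsplit(comp_unit, "")[[1]]
    paste(cu[((seq_len(length) - 1L + frame) %% 3L) + 1L], collapse = "")
}

# Character-level mismatch positions of an arbitrary sequence vs the phased
# repeat complement (used for guides and for sequenced isomiR variants).
mismatch_positions_chr <- function(seq_rna, unit, frame) {
    ref <- complement_reference(unit, nchar(seq_rna), frame)
    which(strsplit(seq_rna, "")[[1]] != strsplit(ref, "")[[1]])
}

#' Mismatch profile of a guide against a repeat target
#'
#' Compares a guide base-by-base with the repeat-complement reference in a
#' given phase (frame 0 starts the CUG reference at C). Pairing is strict
#' Watson-Crick (A-U, G-C); G:U wobble counts as a mismatch, matching
#' DNA-space off-target alignment. Position `p` is reported iff the guide
#' base at `p` differs from the phase-shifted reference at `p`.
#'
#' @param guide A [guide_strand()] or nucleotide string.
#' @param target A [repeat_target()]; its uninterrupted span must be at
#'   least as long as the guide.
#' @param frame `0`, `1`, `2`, or `"best"` (default): the frame minimizing
#'   the mismatch count, ties broken by the lowest frame index.
#' @return Object of class `"mismatch_profile"`: list with `guide_name`,
#'   `frame_offset`, `positions` (sorted 1-based guide positions) and
#'   `count`.
#' @examples
#' mismatch_profile(a2_guide(), repeat_target(28))$positions  # 8
#' @export
mismatch_profile <- function(guide, target, frame = "best") {
    seq <- as_guide_sequence(guide)
    name <- if (inherits(guide, "guide_strand")) guide$name else NA_character_
    stopifnot(inherits(target, "repeat_target"))
    L <- nchar(seq)
    if (3L * target$n_units < L)
        stop("target (", 3L * target$n_units,
             " nt) shorter than guide (", L, " nt): no available register")
    if (identical(frame, "best")) {
        profs <- lapply(0:2, function(f)
            mismatch_positions_chr(seq, target$unit, f))
        frame <- which.min(vapply(profs, length, 0L)) - 1L
        positions <- profs[[frame + 1L]]
    } else {
        frame <- as.integer(frame)
        if (!frame %in% 0:2) stop("frame must be 0, 1, 2 or \"best\"")
        positions <- mismatch_positions_chr(seq, target$unit, frame)
    }
    structure(list(guide_name = name, frame_offset = frame,
                   positions = as.integer(positions),
                   count = length(positions)),
              class = "mismatch_profile")
}

#' @export
print.mismatch_profile <- function(x, ...) {
    cat("mismatch_profile", if (!is.na(x$guide_name)) x$guide_name else "",
        "frame", x$frame_offset, ":",
        if (x$count == 0) "perfect complement"
        else paste(x$positions, collapse = ", "), "\n")
    invisible(x)
}

#' Substitution scan of a guide against a repeat target
#'
#' Enumerates every single-base substitution of the parent (3 alternatives
#' at each of its L positions) and reports the mismatch profile of each
#' variant against the target, in the parent's best frame. This is the
#' design step that identifies positions where an additional mismatch
#' minimizes off-target complementarity while retaining repeat pairing.
#'
#' @param parent A [guide_strand()].
#' @param target A [repeat_target()].
#' @return Data frame with one row per (position, alternative base):
#'   columns `position`, `alt`, `mismatch_positions` (comma-separated),
#'   `mismatch_count`.
#' @export
substitution_scan <- function(parent, target = repeat_target(28)) {
    stopifnot(inherits(parent, "guide_strand"))
    frame <- mismatch_profile(parent, target, "best")$frame_offset
    L <- nchar(parent$sequence)
    rows <- list()
    for (p in seq_len(L)) {
        cur <- substr(parent$sequence, p, p)
        for (b in setdiff(RNA_BASES, cur)) {
            s <- parent$sequence
            substr(s, p, p) <- b
            pos <- mismatch_positions_chr(s, target$unit, frame)
            rows[[length(rows) + 1L]] <-
                data.frame(position = p, alt = b,
                           mismatch_positions = paste(pos, collapse = ","),
                           mismatch_count = length(pos))
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "frame_offset") <- frame
    attr(out, "parent") <- parent$name
    out
}

#' Count in-frame binding registers on a repeat tract
#'
#' Longer repeat tracts offer more in-phase alignment windows for the guide,
#' enabling cooperative binding of multiple silencing complexes. This counts
#' start offsets `o` in `[0, 3n - L]` with `o` a multiple of 3 at which the
#' guide aligns to the tract's complement with at most `max_mismatches`
#' mismatches; 0 when the tract is shorter than the guide.
#'
#' @param target A [repeat_target()].
#' @param guide_length Guide length in nt (used with the default guide).
#' @param max_mismatches Mismatch tolerance per window.
#' @param guide Guide to align; defaults to [a2_guide()]. Its length
#'   overrides `guide_length` when supplied.
#' @return Integer count of qualifying in-frame registers.
#' @examples
#' inframe_register_count(repeat_target(16), 19, 2)  # 10
#' @export
inframe_register_count <- function(target, guide_length = 19L,
                                   max_mismatches = 2L, guide = a2_guide()) {
    stopifnot(inherits(target, "repeat_target"))
    seq <- as_guide_sequence(guide)
    L <- nchar(seq)
    if (!is.null(guide_length) && L != guide_length)
        stop("guide_length (", guide_length,
             ") disagrees with the supplied guide (", L, " nt)")
    total <- 3L * target$n_units
    if (total < L) return(0L)
    # guide faces the reverse complement of the tract, read 5'->3'
    ref_full <- chartr("T", "U",
                       revcomp_dna(repeat_sequence(target, "dna")))
    g <- strsplit(seq, "")[[1]]
    k <- 0L
    for (o in seq.int(0L, total - L, by = 3L)) {
        w <- strsplit(substr(ref_full, o + 1L, o + L), "")[[1]]
        if (sum(g != w) <= max_mismatches) k <- k + 1L
    }
    k
}

#' Read guides from FASTA (plus optional substitution sidecar)
#'
#' @param fasta Path to a FASTA file of guide sequences (U or T accepted).
#' @param tsv Optional path to a TSV sidecar with columns `guide_name`,
#'   `position`, `from`, `to`.
#' @return Named list of [guide_strand()] objects.
#' @export
read_guides <- function(fasta, tsv = NULL) {
    ss <- Biostrings::readBStringSet(fasta)
    subs <- NULL
    if (!is.null(tsv)) {
        subs <- read.delim(tsv, stringsAsFactors = FALSE, comment.char = "#")
        stopifnot(all(c("guide_name", "position", "from", "to") %in%
                          names(subs)))
    }
    out <- lapply(seq_along(ss), function(i) {
        nm <- names(ss)[i]
        s <- if (!is.null(subs) && any(subs$guide_name == nm)) {
            d <- subs[subs$guide_name == nm, c("position", "from", "to")]
            d
        } else NULL
        guide_strand(nm, as.character(ss[[i]]), substitutions = s)
    })
    setNames(out, names(ss))
}

#' Write guides to FASTA plus a substitution sidecar TSV
#'
#' @param guides List of [guide_strand()] objects.
#' @param fasta Output FASTA path (RNA alphabet).
#' @param tsv Optional output TSV path for substitution records.
#' @return Invisibly, `fasta`.
#' @export
write_guides <- function(guides, fasta, tsv = NULL) {
    if (inherits(guides, "guide_strand")) guides <- list(guides)
    seqs <- Biostrings::RNAStringSet(vapply(guides, `[[`, "", "sequence"))
    names(seqs) <- vapply(guides, `[[`, "", "name")
    Biostrings::writeXStringSet(seqs, fasta)
    if (!is.null(tsv)) {
        recs <- do.call(rbind, lapply(guides, function(g) {
            if (nrow(g$substitutions) == 0) return(NULL)
            cbind(guide_name = g$name, g$substitutions)
        }))
        if (is.null(recs))
            recs <- data.frame(guide_name = character(), position = integer(),
                               from = character(), to = character())
        write.table(recs, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(fasta)
}
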
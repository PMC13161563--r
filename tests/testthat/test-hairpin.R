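hp <- amir13a_hairpin()
gs <- hp$guide_arm[1]
guide_seq <- substr(hp$sequence, gs + 1, hp$guide_arm[2])
pass_seq <- substr(hp$sequence, hp$passenger_arm[1] + 1, hp$passenger_arm[2])

test_that("reads are assigned to arms by their longest templated prefix", {
    a <- assign_read(guide_seq, hp)
    expect_equal(a[c("arm", "start_offset", "templated_length")],
                 list(arm = "guide", start_offset = gs,
                      templated_length = 19L))
    # +1 5'-shifted isomiR starts one base earlier on the hairpin
    a1 <- assign_read(substr(hp$sequence, gs, hp$guide_arm[2]), hp)
    expect_equal(a1$arm, "guide")
    expect_equal(a1$start_offset, gs - 1L)
    # up to two non-templated 3' nt join the same group (G does not extend
    # the templated match: the loop starts with T)
    at <- assign_read(paste0(guide_seq, "GG"), hp)
    expect_equal(at[c("arm", "start_offset", "templated_length")],
                 a[c("arm", "start_offset", "templated_length")])
    # a 3-nt foreign tail exceeds the tolerance
    expect_equal(assign_read(paste0(guide_seq, "GGG"), hp)$arm, "unassigned")
    # passenger arm reads
    expect_equal(assign_read(pass_seq, hp)$arm, "passenger")
    # length bounds and foreign reads
    expect_equal(assign_read("ACGTACGTACGTAC", hp)$arm, "unassigned")
    expect_equal(assign_read(strrep("ACGT", 8), hp)$arm, "unassigned")
})

test_that("variant grouping pools minor 5' starts and sums to 100%", {
    reads <- c(rep(guide_seq, 60),
               rep(substr(hp$sequence, gs, hp$guide_arm[2]), 25),
               rep(pass_seq, 15))
    asg <- cagmir:::assign_read_table(read_smallrna(reads), hp)
    groups <- group_variants(asg, hp)
    expect_equal(sum(groups$fraction_of_assigned), 100)
    expect_equal(groups$read_count[groups$start_offset == gs &
                                       !is.na(groups$start_offset)], 60)
    # all identical reads give a single 100% group
    g1 <- group_variants(cagmir:::assign_read_table(
        read_smallrna(rep(guide_seq, 10)), hp), hp)
    expect_equal(nrow(g1), 1L)
    expect_equal(g1$fraction_of_assigned, 100)
    # equal counts: both groups reported, ordered by start offset
    g2 <- group_variants(cagmir:::assign_read_table(read_smallrna(
        c(rep(guide_seq, 10),
          rep(substr(hp$sequence, gs, hp$guide_arm[2]), 10))), hp), hp)
    expect_equal(g2$start_offset, c(gs - 1L, gs))
    expect_equal(g2$read_count, c(10, 10))
    # pooling: a 100th-part group falls under the default 0.5% threshold
    g3 <- group_variants(cagmir:::assign_read_table(read_smallrna(
        c(rep(guide_seq, 999),
          substr(hp$sequence, gs, hp$guide_arm[2]))), hp), hp)
    expect_true(any(is.na(g3$start_offset)))
    expect_equal(sum(g3$fraction_of_assigned), 100)
    # empty library is an error
    empty <- cagmir:::assign_read_table(
        read_smallrna(strrep("ACGT", 8)), hp)
    expect_error(group_variants(empty, hp), "no assigned reads")
})

test_that("strand bias and length distribution summarize assigned reads", {
    mk <- function(n_guide, n_pass) group_variants(
        cagmir:::assign_read_table(read_smallrna(
            c(rep(guide_seq, n_guide), rep(pass_seq, n_pass))), hp), hp)
    expect_equal(strand_bias(mk(10, 0)), c(guide = 100, passenger = 0))
    expect_equal(strand_bias(mk(10, 10)), c(guide = 50, passenger = 50))
    b <- strand_bias(mk(171, 29))
    expect_equal(unname(sum(b)), 100)
    expect_equal(unname(b["guide"]), 85.5)

    # constructed reads of templated lengths 19..23
    reads <- vapply(0:4, function(e)
        substr(hp$sequence, gs + 1, hp$guide_arm[2] + e), "")
    g <- group_variants(cagmir:::assign_read_table(read_smallrna(reads), hp),
                        hp)
    hist <- length_distribution(g)
    expect_equal(names(hist), as.character(19:23))
    expect_equal(unname(hist), rep(1L, 5))
    g1 <- group_variants(cagmir:::assign_read_table(
        read_smallrna(rep(guide_seq, 4)), hp), hp)
    expect_equal(length_distribution(g1), c(`19` = 4L))
})

test_that("top-N fraction is a scale-invariant percentage", {
    endo <- setNames(rep(200, 50), paste0("miR", 1:50))  # top-50 sum 10000
    expect_equal(top_n_fraction(71, endo), 0.71)
    expect_equal(top_n_fraction(0, endo), 0)
    expect_equal(top_n_fraction(710, endo * 10), 0.71)
    # only the N most abundant species count
    endo2 <- c(endo, setNames(rep(1, 30), paste0("lowmiR", 1:30)))
    expect_equal(top_n_fraction(71, endo2), 0.71)
    expect_warning(f <- top_n_fraction(5, setNames(c(50, 50), c("a", "b"))),
                   "fewer than 50")
    expect_equal(f, 5)
    expect_error(top_n_fraction(5, setNames(numeric(0), character(0))),
                 "empty")
    expect_error(top_n_fraction(5, setNames(c(0, 0), c("a", "b"))), "zero")
})

test_that("register mismatches follow the 5' start of each guide variant", {
    reads <- c(rep(guide_seq, 50),                                 # {8,13}
               rep(substr(hp$sequence, gs, hp$guide_arm[2]), 50),  # {9,14}
               rep(pass_seq, 20))
    groups <- annotate_registers(group_variants(
        cagmir:::assign_read_table(read_smallrna(reads), hp), hp))
    canon <- groups[which(groups$start_offset == gs & groups$arm == "guide"), ]
    plus1 <- groups[which(groups$start_offset == gs - 1L), ]
    expect_equal(canon$register_mismatches, "8,13")
    expect_equal(plus1$register_mismatches, "9,14")
    expect_true(all(is.na(groups$register_mismatches[groups$arm ==
                                                         "passenger"])))
    # pure-repeat control guide has an empty register profile
    hp2 <- hairpin_annotation("pure",
                              paste0("ACGGTATG", strrep("CTG", 6), "C",
                                     "TCACATTCA",
                                     oracle_revcomp(paste0(strrep("CTG", 6),
                                                           "C")),
                                     "CCTATGAC"),
                              guide_arm = c(8, 27),
                              passenger_arm = c(36, 55))
    g <- annotate_registers(group_variants(cagmir:::assign_read_table(
        read_smallrna(rep(strrep("CTG", 6), 5)), hp2), hp2))
    expect_equal(g$register_mismatches, "")
})

test_that("generated mixtures are recovered within binomial error", {
    sim <- make_reads(hp, default_mixture(hp, depth = 2e4), seed = 314)
    rep <- process_smallrna(sim$reads, hp, endogenous = sim$endogenous)
    expect_equal(rep$n_assigned + rep$n_unassigned, rep$n_reads_total)
    expect_equal(rep$n_reads_total, 2e4)
    expect_equal(sum(rep$variant_table$fraction_of_assigned), 100,
                 tolerance = 1e-9)
    tol <- function(p) 3 * sqrt(p * (1 - p) / 2e4) * 100
    expect_equal(unname(rep$strand_bias["guide"]), 85.5,
                 tolerance = tol(0.855) / 85.5)
    vt <- rep$variant_table
    frac_at <- function(off) vt$fraction_of_assigned[
        !is.na(vt$start_offset) & vt$start_offset == off]
    expect_equal(frac_at(gs - 1L), 35.9, tolerance = tol(0.359) / 35.9)
    expect_equal(frac_at(gs), 32.4, tolerance = tol(0.324) / 32.4)
    # reports are deterministic for identical input and configuration
    rep2 <- process_smallrna(sim$reads, hp, endogenous = sim$endogenous)
    expect_identical(rep, rep2)
})

test_that("small-RNA input formats are read equivalently", {
    tmp <- withr::local_tempdir()
    sim <- make_reads(hp, default_mixture(hp, depth = 500), seed = 9,
                      fastq = file.path(tmp, "r.fastq"))
    tab_mem <- read_smallrna(sim$reads)
    tab_fq <- read_smallrna(file.path(tmp, "r.fastq"))
    expect_equal(tab_fq, tab_mem)
    collapsed <- file.path(tmp, "r.tsv")
    write.table(tab_mem, collapsed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    expect_equal(read_smallrna(collapsed), tab_mem)
    # report written twice is byte-identical
    r1 <- process_smallrna(file.path(tmp, "r.fastq"), hp)
    f1 <- file.path(tmp, "rep1.tsv"); f2 <- file.path(tmp, "rep2.tsv")
    write_processing_report(r1, f1)
    write_processing_report(process_smallrna(file.path(tmp, "r.fastq"), hp),
                            f2)
    expect_identical(readLines(f1), readLines(f2))
})
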
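test_that("target sites are reverse complements of their guides", {
    expect_equal(make_target_site(a2_guide())$site_sequence,
                 "GCAGCAGCAGCTGCAGCAG")
    expect_equal(make_target_site("CUGCUGCUGCUGCUGCUGC")$site_sequence,
                 "GCAGCAGCAGCAGCAGCAG")
    g13a <- designed_guides()$`13A`
    site <- make_target_site(g13a)$site_sequence
    expect_equal(site, "GCAGCATCAGCTGCAGCAG")
    expect_equal(site, oracle_revcomp(chartr("U", "T", g13a$sequence)))
    # reverse-complementing twice recovers the guide in DNA space
    expect_equal(oracle_revcomp(site), chartr("U", "T", g13a$sequence))
    expect_error(make_target_site("CUGCUGNAGCUGCUGCUGC"), "non-RNA")
})

test_that("scan recovers a planted site and repeat-tract registers", {
    set.seed(101)
    bg <- random_dna(200)
    site <- make_target_site(a2_guide())$site_sequence
    substr(bg, 51, 69) <- site
    h <- scan_offtargets(c(chr = bg), a2_guide(), budget = 0)
    expect_equal(nrow(h), 1L)
    expect_equal(h$start, 50L)
    expect_equal(h$end, 69L)
    expect_equal(h$mismatch_count, 0L)
    expect_equal(h$site_observed, site)

    # pure CAG tract: the position-8 interruption forces one mismatch in
    # every in-frame register and defeats budget 0
    tract <- strrep("CAG", 30)
    h1 <- scan_offtargets(c(t = tract), a2_guide(), budget = 1,
                          strands = "sense")
    orc <- oracle_scan(tract, site, 1, strands = "sense")
    expect_equal(hit_key(h1), hit_key(orc))
    expect_true(all(h1$mismatch_count == 1L))
    # hits fall on every in-frame register (one fixed phase of the repeat)
    expect_equal(length(unique(h1$start %% 3)), 1L)
    expect_equal(nrow(h1), 24L)  # floor((90 - 19 - 2) / 3) + 1 registers
    expect_equal(unique(h1$mismatch_positions), "8")
    h0 <- scan_offtargets(c(t = tract), a2_guide(), budget = 0,
                          strands = "sense")
    expect_equal(nrow(h0), 0L)
    expect_error(scan_offtargets(c(t = tract), a2_guide(), budget = 4),
                 "budget")
})

test_that("seeded scanner equals the naive oracle on random sequences", {
    site <- make_target_site(designed_guides()$`13A`)
    set.seed(202)
    for (rep in 1:12) {
        text <- random_dna(sample(500:2000, 1), prob = c(0.2, 0.3, 0.3, 0.2))
        # salt with repeat-like content so near-misses exist
        at <- sample(100:300, 1)
        substr(text, at, at + 29) <- strrep("CAG", 10)
        for (budget in 0:3) {
            for (mode in c("both", "sense")) {
                got <- scan_offtargets(c(s = text), site, budget = budget,
                                       strands = mode)
                gotn <- scan_offtargets(c(s = text), site, budget = budget,
                                        strands = mode, method = "naive")
                orc <- oracle_scan(text, site$site_sequence, budget,
                                   strands = mode)
                expect_equal(hit_key(got), hit_key(orc))
                expect_equal(hit_key(gotn), hit_key(orc))
            }
        }
    }
})

test_that("reported mismatch positions are in guide coordinates", {
    # a site with one planted mismatch: position within the site maps back
    # to the guide 5'-based coordinate on both strands
    site <- make_target_site(a2_guide())$site_sequence
    mut <- site
    substr(mut, 3, 3) <- "T"  # site index 3 -> guide position 19 + 1 - 3 = 17
    hp <- scan_offtargets(c(s = mut), a2_guide(), budget = 1,
                          strands = "sense")
    expect_equal(hp$mismatch_positions, "17")
    hm <- scan_offtargets(c(s = oracle_revcomp(mut)), a2_guide(), budget = 1)
    hm <- hm[hm$strand == "-", ]
    expect_equal(hm$mismatch_positions, "17")
})

test_that("both-strand scanning is symmetric under reverse complement", {
    set.seed(303)
    for (rep in 1:5) {
        text <- random_dna(1500, prob = c(0.2, 0.3, 0.3, 0.2))
        at <- sample(200:800, 1)
        substr(text, at, at + 18) <- make_target_site(a2_guide())$site_sequence
        h <- scan_offtargets(c(s = text), a2_guide(), budget = 2)
        hr <- scan_offtargets(c(s = oracle_revcomp(text)), a2_guide(),
                              budget = 2)
        n <- nchar(text)
        reflected <- data.frame(strand = ifelse(hr$strand == "+", "-", "+"),
                                start = n - hr$end,
                                mismatch_count = hr$mismatch_count)
        expect_equal(hit_key(h), hit_key(reflected))
    }
})

test_that("windows containing N are skipped and tallied", {
    set.seed(404)
    bg <- random_dna(200)
    site <- make_target_site(a2_guide())$site_sequence
    substr(bg, 51, 69) <- site
    substr(bg, 60, 60) <- "N"
    h <- scan_offtargets(c(s = bg), a2_guide(), budget = 3)
    expect_false(any(h$start < 69 & h$end > 50))  # planted window gone
    expect_equal(attr(h, "skipped_windows"), 19L)
    hn <- scan_offtargets(c(s = bg), a2_guide(), budget = 3,
                          method = "naive")
    expect_equal(attr(hn, "skipped_windows"), 19L)
})

test_that("overlapping windows merge into loci like the interval oracle", {
    tract <- strrep("CAG", 30)
    h <- scan_offtargets(c(t = tract), a2_guide(), budget = 1,
                         strands = "sense")
    loci <- merge_loci(h)
    expect_equal(nrow(loci), 1L)
    expect_equal(loci$n_windows, nrow(h))
    expect_equal(loci$min_mismatch_count, 1L)
    orc <- oracle_merge(h$start, h$end)
    expect_equal(c(loci$start, loci$end), c(orc[1, 1], orc[1, 2]))

    # disjoint plants stay separate
    set.seed(505)
    bg <- random_dna(400)
    site <- make_target_site(a2_guide())$site_sequence
    for (at in c(11, 101, 301)) substr(bg, at, at + 18) <- site
    h3 <- scan_offtargets(c(s = bg), a2_guide(), budget = 0)
    expect_equal(nrow(merge_loci(h3)), 3L)

    expect_equal(nrow(merge_loci(h3[0, ])), 0L)

    # random windows vs the oracle (same sequence and strand)
    set.seed(506)
    for (rep in 1:10) {
        st <- sample(0:300, 20, replace = TRUE)
        hits <- data.frame(sequence_id = "s", strand = "+", start = st,
                           end = st + 19L, mismatch_count = 1L,
                           guide_name = "g")
        got <- merge_loci(hits)
        orc <- oracle_merge(hits$start, hits$end)
        expect_equal(as.matrix(got[c("start", "end")]), orc,
                     ignore_attr = TRUE)
        expect_equal(sum(got$n_windows), nrow(hits))
    }
})

test_that("loci are annotated with every overlapping region type", {
    loci <- data.frame(sequence_id = c("c1", "c1", "c1", "c2"),
                       strand = "+",
                       start = c(100L, 190L, 400L, 5L),
                       end = c(119L, 209L, 419L, 24L),
                       n_windows = 1L, min_mismatch_count = 0L,
                       guide_name = "A2")
    regions <- data.frame(sequence_id = "c1",
                          start = c(90L, 200L), end = c(200L, 300L),
                          type = c("CDS", "3UTR"))
    ann <- annotate_loci(loci, regions)
    expect_equal(ann$region_labels,
                 c("CDS", "3UTR,CDS", "intergenic", "intergenic"))
    expect_warning(annotate_loci(loci,
                                 rbind(regions,
                                       data.frame(sequence_id = "c9",
                                                  start = 0L, end = 10L,
                                                  type = "CDS"))),
                   "unknown sequence_id")
})

test_that("summaries bin each transcript once at its minimum distance", {
    site13a <- make_target_site(designed_guides()$`13A`)$site_sequence
    set.seed(606)
    mk_tx <- function(k) {
        s <- site13a
        if (k > 0) {
            pos <- sample(19, k)
            for (p in pos)
                substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                  substr(s, p, p)), 1)
        }
        tx <- random_dna(150)
        substr(tx, 61, 79) <- s
        tx
    }
    txs <- c(replicate(3, mk_tx(0)), replicate(5, mk_tx(1)),
             replicate(7, mk_tx(2)))
    names(txs) <- paste0("tx", seq_along(txs))
    # construction check: each transcript's min distance is as planted
    planted_k <- rep(c(0, 1, 2), c(3, 5, 7))
    for (i in seq_along(txs)) {
        orc <- oracle_scan(txs[i], site13a, 2, strands = "sense")
        expect_equal(min(orc$mismatch_count), planted_k[i])
    }
    summ <- summarize_offtargets(designed_guides()$`13A`, txs, budget = 2,
                                 level = "transcript")
    expect_equal(unlist(summ[c("k0", "k1", "k2")], use.names = FALSE),
                 c(3L, 5L, 7L))
    expect_true(is.na(summ$k3))
    # cumulative counts are non-decreasing in the threshold
    cum <- cumsum(unlist(summ[c("k0", "k1", "k2")]))
    expect_true(all(diff(cum) >= 0))

    empty <- summarize_offtargets(designed_guides()$`13A`, character(0),
                                  budget = 2, level = "transcript")
    expect_equal(unlist(empty[c("k0", "k1", "k2")], use.names = FALSE),
                 c(0L, 0L, 0L))
})

test_that("guides rank lexicographically on exact-mismatch counts", {
    summ <- data.frame(guide_name = c("A", "B", "C"), level = "transcript",
                       k0 = c(0L, 0L, 1L), k1 = c(2L, 1L, 0L),
                       k2 = c(9L, 30L, 0L), k3 = NA_integer_)
    expect_equal(rank_guides(summ)$guide_name, c("B", "A", "C"))
    tie <- data.frame(guide_name = c("z", "a"), level = "transcript",
                      k0 = 1L, k1 = 1L, k2 = 1L, k3 = NA_integer_)
    expect_equal(rank_guides(tie)$guide_name, c("a", "z"))
    single <- summ[1, ]
    expect_equal(rank_guides(single)$guide_name, "A")
    mixed <- summ
    mixed$level <- c("transcript", "locus", "transcript")
    expect_error(rank_guides(mixed), "mix levels")
    mixed2 <- summ
    mixed2$k3 <- c(1L, NA, NA)
    expect_error(rank_guides(mixed2), "mix budgets")
})

test_that("hits serialize to BED6 with a parameter header", {
    set.seed(707)
    bg <- random_dna(200)
    substr(bg, 51, 69) <- make_target_site(a2_guide())$site_sequence
    h <- scan_offtargets(c(chr1 = bg), a2_guide(), budget = 1)
    tmp <- withr::local_tempfile(fileext = ".bed")
    write_hits_bed(h, tmp)
    lines <- readLines(tmp)
    expect_true(any(grepl("^# budget=1", lines)))
    body <- lines[!grepl("^#", lines)]
    expect_equal(length(body), nrow(h))
    f <- strsplit(body[1], "\t")[[1]]
    expect_equal(length(f), 6L)
    expect_equal(f[1], "chr1")
    expect_equal(f[4], paste0("A2:", h$mismatch_count[1]))
})
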
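# Explicit geometry: a 30 kb "genome" split into two contigs with a 2 kb gap,
# and a 12 kb local unit spanning the gap.
merge_fixture <- function(seed = 501) {
    set.seed(seed)
    G <- rnd_seq(30000)
    list(G = G,
         contigs = seq_set(c("A", "B"),
                           c(substr(G, 1, 12000), substr(G, 14001, 30000))),
         units = local({
             u <- seq_set("unit.1", substr(G, 7001, 19000))
             u$circular <- FALSE
             u
         }))
}

test_that("a unit bridging two contig ends produces an exact merge", {
    fx <- merge_fixture()
    hits <- align_all(fx$contigs, fx$units)
    dec <- propose_merges(fx$units, fx$contigs, hits)
    acc <- dec[dec$accepted, ]
    expect_equal(nrow(acc), 1)
    expect_equal(acc$left_contig_id, "A")
    expect_equal(acc$right_contig_id, "B")
    merged <- apply_merge(acc, fx$contigs, fx$units)
    expect_equal(merged$seq, fx$G) # gap restored exactly
    expect_equal(merged$id, "A+B")
})

test_that("an overlap between contigs appears once in the merge", {
    set.seed(502)
    G <- rnd_seq(30000)
    contigs <- seq_set(c("A", "B"), # A and B share G[13001..14000]
                       c(substr(G, 1, 14000), substr(G, 13001, 30000)))
    units <- seq_set("unit.1", substr(G, 8001, 20000))
    units$circular <- FALSE
    hits <- align_all(contigs, units)
    dec <- propose_merges(units, contigs, hits)
    acc <- dec[dec$accepted, ]
    expect_equal(nrow(acc), 1)
    merged <- apply_merge(acc, contigs, units)
    expect_equal(merged$seq, G)
})

test_that("merging is strand-symmetric", {
    fx <- merge_fixture(503)
    flipped <- fx$contigs
    flipped$seq[2] <- revcomp(flipped$seq[2])
    hits <- align_all(flipped, fx$units)
    dec <- propose_merges(fx$units, flipped, hits)
    acc <- dec[dec$accepted, ]
    expect_equal(nrow(acc), 1)
    merged <- apply_merge(acc, flipped, fx$units)
    expect_equal(merged$seq, fx$G)
})

test_that("merge rejections fire for each stated criterion", {
    set.seed(504)
    G <- rnd_seq(30000)
    contigs <- seq_set(c("A", "B"),
                       c(substr(G, 1, 12000), substr(G, 14001, 30000)))
    # B-side match only 3500 bp (< 4000)
    u_short <- seq_set("unit.1", substr(G, 7001, 17500))
    u_short$circular <- FALSE
    dec <- propose_merges(u_short, contigs, align_all(contigs, u_short))
    expect_equal(dec$reason[1], "min_match_len")
    expect_false(any(dec$accepted))
    # both end matches on the same contig
    u_same <- seq_set("unit.1",
                      paste0(substr(G, 1, 5000), rnd_seq(1500),
                             substr(G, 6001, 11000)))
    u_same$circular <- FALSE
    dec <- propose_merges(u_same, contigs, align_all(contigs, u_same))
    expect_true(all(dec$reason %in% c("same_contig", "single_end_match")))
    # A-side interval too far from either contig end
    big <- seq_set(c("A", "B"), c(rnd_seq(40000), substr(G, 14001, 30000)))
    u_mid <- seq_set("unit.1", paste0(substr(big$seq[1], 10001, 15000),
                                      substr(G, 14001, 19000)))
    u_mid$circular <- FALSE
    dec <- propose_merges(u_mid, big, align_all(big, u_mid))
    expect_equal(dec$reason[1], "contig_end_dist")
    # a longer hit elsewhere vetoes the pair
    fx <- merge_fixture(505)
    decoy <- rbind(fx$contigs,
                   seq_set("C", paste0(rnd_seq(500),
                                       substr(fx$units$seq, 3001, 9500),
                                       rnd_seq(500))))
    class(decoy) <- class(fx$contigs)
    dec <- propose_merges(fx$units, decoy, align_all(decoy, fx$units))
    expect_equal(dec$reason[1], "longer_hit_elsewhere")
    expect_false(any(dec$accepted))
})

test_that("fragmented circles merge to one contig at the fixpoint", {
    ts <- sim1("fragmented", 50000, 506, n = 3, gap = 500,
               read_length = 4000)
    pp <- pipeline_params(b2r_length_cutoff = 10000, b2r_end_window = 4000)
    mg <- merge_to_fixpoint(ts$contigs, ts$reads, filter_p = pp$filter,
                            merge_p = pp$merge)
    expect_equal(nrow(mg$contigs), 1)
    expect_equal(sum(mg$log$merges_applied), 2)
    # the merged contig is a near-complete arc of the circle (only the
    # junction between the outermost arcs is still open), every base of it
    # attributable to the truth
    dd <- strrep(ts$truth$seq, 2)
    expect_true(grepl(mg$contigs$seq, dd, fixed = TRUE) ||
                grepl(revcomp(mg$contigs$seq), dd, fixed = TRUE))
    expect_gte(nchar(mg$contigs$seq), 48000)
    expect_lte(nchar(mg$contigs$seq), 50000)
    # merge decisions never depend on contig order
    shuf <- ts$contigs[c(2, 3, 1), ]
    class(shuf) <- class(ts$contigs)
    mg2 <- merge_to_fixpoint(shuf, ts$reads, filter_p = pp$filter,
                             merge_p = pp$merge)
    expect_equal(nrow(mg2$contigs), 1)
    expect_equal(nchar(mg2$contigs$seq), nchar(mg$contigs$seq))
})

test_that("an already-merged assembly is a fixpoint after one iteration", {
    ts <- sim1("none", 20000, 507)
    mg <- merge_to_fixpoint(ts$contigs, ts$reads,
                            filter_p = filter_params(length_cutoff = 3e5))
    expect_equal(sum(mg$log$merges_applied), 0)
    expect_equal(mg$n_iterations, 1)
    expect_equal(mg$contigs$seq, ts$contigs$seq)
})
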
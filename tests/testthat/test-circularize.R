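test_that("a tandem multi-copy contig is replaced by its circular unit", {
    set.seed(601)
    P <- rnd_seq(4000)
    contig <- seq_set("tandem", substr(strrep(P, 3), 1, 9200)) # 2.3 copies
    unit <- seq_set("unit.1", rotate(P, 1500), circular = TRUE)
    hits <- align_all(contig, unit)
    res <- circularize_by_replacement(contig, unit, hits)
    expect_equal(res$action, "replaced")
    expect_equal(nchar(res$contig$seq), 4000)
    expect_true(grepl(res$contig$seq, strrep(P, 2), fixed = TRUE))
})

test_that("replacement requires one unit hit of at least min_unit_frac", {
    set.seed(602)
    P <- rnd_seq(4000)
    # 1.5 copies: a unit linearized 2500 in never matches in one piece
    contig <- seq_set("c", substr(strrep(P, 2), 1, 6000))
    unit <- seq_set("unit.1", rotate(P, 2500), circular = TRUE)
    hits <- align_all(contig, unit)
    expect_gte(interval_union_len <- sum(hits$ref_end - hits$ref_start), 6000)
    expect_lt(max(hits$qry_end - hits$qry_start), 0.95 * 4000)
    expect_equal(circularize_by_replacement(contig, unit, hits)$action,
                 "unchanged")
    # ... while a unit matching in one full-length piece is accepted
    unit0 <- seq_set("unit.1", P, circular = TRUE)
    hits0 <- align_all(contig, unit0)
    expect_equal(circularize_by_replacement(contig, unit0, hits0)$action,
                 "replaced")
})

test_that("coverage split across two different units does not replace", {
    set.seed(603)
    P <- rnd_seq(8000)
    contig <- seq_set("c", P)
    units <- seq_set(c("unit.1", "unit.2"),
                     c(substr(P, 1, 4200), substr(P, 4001, 8000)),
                     circular = TRUE)
    hits <- align_all(contig, units)
    expect_equal(circularize_by_replacement(contig, units, hits)$action,
                 "unchanged")
})

test_that("end-join resolves duplicated and missing junctions exactly", {
    # duplicated low-quality ends
    ts <- sim1("dup_ends", 20000, 604, len = 2000)
    res <- run_pipeline(ts$contigs, ts$reads, plasmid_params())
    sc <- score_against_truth(res$contigs, ts)
    expect_true(all(sc$report$correctly_circularized))
    # missing junction sequence is restored from the unit
    ts2 <- sim1("missing", 20000, 605, len = 1500)
    res2 <- run_pipeline(ts2$contigs, ts2$reads, plasmid_params())
    expect_equal(res2$circularize_report$action, "end_joined")
    sc2 <- score_against_truth(res2$contigs, ts2)
    expect_equal(sc2$report$length_delta, 0)
    expect_true(all(sc2$report$correctly_circularized))
})

test_that("start- and end-matches on different units leave the contig alone", {
    set.seed(606)
    G <- rnd_seq(20000)
    contig <- seq_set("c", G)
    units <- seq_set(c("unit.1", "unit.2"),
                     c(substr(G, 1, 6000), substr(G, 14001, 20000)))
    units$circular <- FALSE
    hits <- align_all(contig, units)
    res <- circularize_by_end_join(contig, units, hits)
    expect_equal(res$action, "unchanged")
})

test_that("repeat-flanked linear contigs are not circularized", {
    for (rl in c(2000, 8000)) {
        ts <- sim1("false_overlap", 30000, 607 + rl, repeat_len = rl)
        res <- run_pipeline(ts$contigs, ts$reads, plasmid_params())
        expect_equal(sum(res$contigs$circular), 0)
        expect_equal(res$circularize_report$action, "unchanged")
        expect_equal(res$contigs$seq, ts$contigs$seq) # byte-identical passthrough
    }
})

test_that("circularized output never contains its junction twice", {
    for (fix in list(list("dup_ends", 20000, 608, list(len = 2000)),
                     list("tandem", 4000, 609, list(copies = 3)))) {
        ts <- do.call(sim1, c(fix[[1]], fix[[2]], fix[[3]], fix[[4]]))
        res <- run_pipeline(ts$contigs, ts$reads, plasmid_params())
        out <- res$contigs
        expect_true(all(out$circular))
        self <- align_all(out, out)
        self <- self[!(self$ref_start == self$qry_start &
                       self$ref_end == self$qry_end & self$strand == "+"), ]
        L <- nchar(out$seq)
        endstart <- self[self$ref_start <= 100 & L - self$qry_end <= 100 &
                         self$aln_len >= 4000, ]
        expect_equal(nrow(endstart), 0)
    }
})

test_that("contigs already flagged circular pass through untouched", {
    set.seed(610)
    ctg <- seq_set("done", rnd_seq(9000), circular = TRUE)
    units <- seq_set("unit.1", ctg$seq, circular = TRUE)
    res <- circularize_contigs(ctg, units)
    expect_equal(res$report$action, "already_circular")
    expect_equal(res$contigs$seq, ctg$seq)
})
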
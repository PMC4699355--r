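# Hits are constructed directly (the filter consumes any aligner's output),
# so window logic is tested in isolation from the aligner.
mk_hit <- function(rid, cid, rs, re, qs, qe, strand = "+", clen, qlen) {
    data.frame(ref_id = cid, qry_id = rid, ref_start = rs, ref_end = re,
               qry_start = qs, qry_end = qe, strand = strand, pct_id = 100,
               aln_len = re - rs, ref_len = clen, qry_len = qlen,
               stringsAsFactors = FALSE)
}

test_that("end-window rules match the stated boundary behavior", {
    set.seed(301)
    clen <- 200000
    contig <- seq_set("big", strrep("ACGT", clen / 4))
    reads <- seq_set(c("inwin", "boundary", "interior", "longcross"),
                     c(rnd_seq(5000), rnd_seq(500), rnd_seq(5000), rnd_seq(9000)))
    hits <- rbind(
        mk_hit("inwin", "big", 10, 5010, 0, 5000, clen = clen, qlen = 5000),
        mk_hit("boundary", "big", 49900, 50400, 0, 500, clen = clen, qlen = 500),
        mk_hit("interior", "big", 80000, 85000, 0, 5000, clen = clen, qlen = 5000),
        mk_hit("longcross", "big", 46000, 55000, 0, 9000, clen = clen, qlen = 9000))
    out <- filter_reads(reads, contig, hits)
    expect_true("inwin" %in% out$id) # wholly in window: kept whole
    expect_false(out$trimmed[out$id == "inwin"])
    expect_equal(out$origin[out$id == "inwin"], "end_window")
    # 100 bases inside the window < 250 minimum: discarded
    expect_false("boundary" %in% out$id)
    expect_false("interior" %in% out$id)
    # 4000 bases inside the window: kept, trimmed
    lc <- out[out$id == "longcross", ]
    expect_true(lc$trimmed)
    expect_equal(nchar(lc$seq), 4000)
    expect_equal(lc$seq, substr(reads$seq[reads$id == "longcross"], 1, 4000))
})

test_that("short-contig and unmapped reads are retained whole", {
    set.seed(302)
    contig <- seq_set("small", rnd_seq(50000))
    reads <- seq_set(c("mapped", "stray"), c(rnd_seq(3000), rnd_seq(800)))
    hits <- mk_hit("mapped", "small", 20000, 23000, 0, 3000,
                   clen = 50000, qlen = 3000)
    out <- filter_reads(reads, contig, hits)
    expect_equal(out$origin[out$id == "mapped"], "short_contig")
    expect_equal(out$origin[out$id == "stray"], "unmapped")
    expect_equal(out$seq, reads$seq)
})

test_that("minus-strand trimming cuts the correct read side", {
    set.seed(303)
    clen <- 200000
    contig <- seq_set("big", strrep("ACGT", clen / 4))
    reads <- seq_set("rc", rnd_seq(9000))
    hits <- mk_hit("rc", "big", 46000, 55000, 0, 9000, strand = "-",
                   clen = clen, qlen = 9000)
    out <- filter_reads(reads, contig, hits)
    # contig [46000, 50000) maps to the READ's last 4000 forward bases
    expect_equal(nchar(out$seq), 4000)
    expect_equal(out$seq, substr(reads$seq[1], 5001, 9000))
})

test_that("a read spanning both windows yields two suffixed records", {
    clen <- 100000 # windows [0, 50k) and [50k, 100k) meet in the middle
    set.seed(304)
    contig <- seq_set("c", strrep("AC", clen / 2))
    reads <- seq_set("both", rnd_seq(20000))
    hits <- mk_hit("both", "c", 40000, 60000, 0, 20000, clen = clen,
                   qlen = 20000)
    out <- filter_reads(reads, contig, hits)
    expect_setequal(out$id, c("both.left", "both.right"))
    expect_equal(out$source_read, c("both", "both"))
    expect_true(all(out$trimmed))
    expect_equal(sort(nchar(out$seq)), c(10000, 10000))
})

test_that("filter agrees with a per-base brute-force oracle", {
    # oracle: for each read, count hit bases inside each window directly
    set.seed(305)
    clen <- 40000
    params <- filter_params(length_cutoff = 30000, end_window = 8000,
                            min_trimmed_len = 250)
    contig <- seq_set("c", strrep("ACGT", clen / 4))
    n <- 100
    rs <- pmin(sample(0:(clen - 300), n), clen - 2000)
    re <- pmin(rs + sample(300:6000, n, replace = TRUE), clen)
    reads <- seq_set(sprintf("r%03d", 1:n),
                     vapply(re - rs, rnd_seq, ""))
    hits <- do.call(rbind, lapply(1:n, function(i)
        mk_hit(sprintf("r%03d", i), "c", rs[i], re[i], 0, re[i] - rs[i],
               clen = clen, qlen = re[i] - rs[i])))
    out <- filter_reads(reads, contig, hits, params)
    W <- params$end_window; ws <- clen - W
    for (i in 1:n) {
        id <- sprintf("r%03d", i)
        pos <- rs[i]:(re[i] - 1)
        in_s <- sum(pos < W); in_e <- sum(pos >= ws)
        recs <- out[out$source_read == id, , drop = FALSE]
        if (in_s == 0 && in_e == 0) {
            expect_equal(nrow(recs), 0)
        } else if (in_s == length(pos) || in_e == length(pos)) {
            expect_equal(recs$seq, reads$seq[i]) # wholly inside: whole read
        } else {
            keep <- c(if (in_s > 0) in_s, if (in_e > 0) in_e)
            keep <- keep[keep >= params$min_trimmed_len]
            expect_equal(sort(nchar(recs$seq)), sort(keep))
        }
    }
})

test_that("growing the end window never shrinks the retained set", {
    set.seed(306)
    clen <- 40000
    contig <- seq_set("c", strrep("ACGT", clen / 4))
    n <- 60
    rs <- sample(0:(clen - 3000), n)
    re <- pmin(rs + sample(500:4000, n, replace = TRUE), clen)
    reads <- seq_set(sprintf("r%03d", 1:n), vapply(re - rs, rnd_seq, ""))
    hits <- do.call(rbind, lapply(1:n, function(i)
        mk_hit(sprintf("r%03d", i), "c", rs[i], re[i], 0, re[i] - rs[i],
               clen = clen, qlen = re[i] - rs[i])))
    prev <- character(0)
    for (W in c(2000, 5000, 10000, 20000)) {
        out <- filter_reads(reads, contig, hits,
                            filter_params(length_cutoff = 30000,
                                          end_window = W))
        expect_true(all(prev %in% out$source_read))
        prev <- out$source_read
    }
})
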
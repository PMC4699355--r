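test_that("self-alignment yields one full-length perfect hit", {
    set.seed(201)
    s <- rnd_seq(5000)
    h <- align_all(seq_set("r", s), seq_set("q", s))
    expect_equal(nrow(h), 1)
    expect_equal(h$ref_start, 0)
    expect_equal(h$ref_end, 5000)
    expect_equal(h$strand, "+")
    expect_equal(h$pct_id, 100)
    expect_equal(h$aln_len, 5000)
})

test_that("a reverse-complemented planted interval is recovered exactly", {
    set.seed(202)
    s <- rnd_seq(5000)
    q <- seq_set("q", revcomp(substr(s, 1001, 3000)))
    h <- align_all(seq_set("r", s), q)
    expect_equal(nrow(h), 1)
    expect_equal(c(h$ref_start, h$ref_end), c(1000, 3000))
    expect_equal(c(h$qry_start, h$qry_end), c(0, 2000))
    expect_equal(h$strand, "-")
    expect_equal(h$pct_id, 100)
})

test_that("mutated queries are recovered with identity matching an
           independent alignment oracle", {
    set.seed(203)
    s <- rnd_seq(4000)
    ch <- strsplit(s, "")[[1]]
    idx <- sample(4000, 120) # 3 % substitutions
    ch[idx] <- vapply(ch[idx],
                      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                      "")
    q <- paste(ch, collapse = "")
    h <- align_all(seq_set("r", s), seq_set("q", q),
                   align_params(min_pct_id = 95))
    expect_gte(sum(h$ref_end - h$ref_start) / 4000, 0.95)
    expect_true(all(h$pct_id >= 95))
    # oracle: Smith-Waterman on the planted pair
    pw <- Biostrings::pairwiseAlignment(q, s, type = "global")
    oracle_pct <- 100 * Biostrings::nmatch(pw) / Biostrings::nchar(pw)
    expect_equal(max(h$pct_id), oracle_pct, tolerance = 0.2)
    # a stricter threshold drops coverage
    h99 <- align_all(seq_set("r", s), seq_set("q", q),
                     align_params(min_pct_id = 99))
    expect_lt(sum(h99$ref_end - h99$ref_start),
              sum(h$ref_end - h$ref_start))
})

test_that("every planted interval above thresholds is recovered", {
    set.seed(204)
    for (rep in 1:5) {
        s <- rnd_seq(2000)
        from <- sample(1000, 1)
        len <- sample(200:900, 1)
        q <- substr(s, from, from + len - 1)
        if (runif(1) < 0.5) q <- revcomp(q)
        h <- align_all(seq_set("r", s), seq_set("q", q),
                       align_params(min_hit_len = 100))
        expect_gte(max(h$aln_len), len)
    }
})

test_that("strand symmetry: reverse-complementing queries flips hits", {
    set.seed(205)
    s <- rnd_seq(3000)
    q <- paste0(rnd_seq(200), substr(s, 501, 1700), rnd_seq(150))
    hf <- align_all(seq_set("r", s), seq_set("q", q))
    hr <- align_all(seq_set("r", s), seq_set("q", revcomp(q)))
    expect_equal(nrow(hf), nrow(hr))
    expect_equal(hf$ref_start, hr$ref_start)
    expect_equal(hf$ref_end, hr$ref_end)
    expect_equal(nchar(q) - hf$qry_end, hr$qry_start)
    expect_true(all(hf$strand != hr$strand))
})

test_that("filter_hits thresholds on unrounded identity and is idempotent", {
    h <- rbind(
        data.frame(ref_id = "r", qry_id = "a", ref_start = 0L, ref_end = 100L,
                   qry_start = 0L, qry_end = 100L, strand = "+", pct_id = 96,
                   aln_len = 100L, ref_len = 1000L, qry_len = 100L),
        data.frame(ref_id = "r", qry_id = "b", ref_start = 0L, ref_end = 100L,
                   qry_start = 0L, qry_end = 100L, strand = "+", pct_id = 94,
                   aln_len = 100L, ref_len = 1000L, qry_len = 100L))
    expect_equal(filter_hits(h, 95)$qry_id, "a")
    expect_equal(filter_hits(h, 0), h)
    expect_equal(filter_hits(h, 95), filter_hits(filter_hits(h, 95), 95))
    expect_equal(nrow(filter_hits(h[1, ], 96)), 1) # >= is inclusive
})

test_that("coords files round-trip and use 1-based show-coords conventions", {
    set.seed(206)
    s <- rnd_seq(2000)
    q <- seq_set(c("qf", "qr"),
                 c(substr(s, 101, 600), revcomp(substr(s, 901, 1400))))
    h <- align_all(seq_set("r", s), q)
    f <- withr::local_tempfile(fileext = ".coords")
    write_coords(h, f)
    tab <- read.table(f, sep = "\t")
    fwd <- tab[tab$V12 == "qf", ]
    expect_equal(c(fwd$V1, fwd$V2), c(101, 600)) # 1-based inclusive
    expect_true(all(fwd$V3 < fwd$V4))
    rev <- tab[tab$V12 == "qr", ]
    expect_true(all(rev$V3 > rev$V4)) # reverse = descending qry coords
    rt <- read_coords(f)
    expect_equal(rt[, setdiff(names(rt), "pct_id")],
                 h[, setdiff(names(h), "pct_id")])
    expect_equal(rt$pct_id, h$pct_id, tolerance = 0.005)
    # malformed rows are reported with their number
    writeLines(c(paste(c(1, 100, 1, 100, 100, 100, "99.00", 200, 100, "+",
                         "r", "q"), collapse = "\t"), "garbage row"), f)
    expect_error(read_coords(f), "parse error")
})

test_that("read_coords handles empty files", {
    f <- withr::local_tempfile()
    file.create(f)
    expect_equal(nrow(read_coords(f)), 0)
})

test_that("translated search finds planted genes in all frames and strands", {
    set.seed(207)
    gene <- paste0("ATG", rnd_seq(297))
    for (off in c(300, 301, 302)) { # all three frames
        ctg <- seq_set("c", paste0(rnd_seq(off), gene, rnd_seq(200)))
        h <- align_translated(ctg, seq_set("g", gene), 80)
        expect_equal(h$ref_start, off)
        expect_equal(h$ref_end, off + 300)
        expect_equal(h$strand, "+")
        expect_equal(h$pct_id, 100)
    }
    ctg <- seq_set("c", paste0(rnd_seq(311), revcomp(gene), rnd_seq(200)))
    h <- align_translated(ctg, seq_set("g", gene), 80)
    expect_equal(c(h$ref_start, h$ref_end, h$strand), c("311", "611", "-"))
})

test_that("synonymous codon changes keep amino-acid identity at 100", {
    set.seed(208)
    gene <- paste0("ATG", paste(sample(setdiff(
        apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                          c("A","C","G","T")), 1, paste, collapse = ""),
        c("TAA", "TAG", "TGA")), 120, replace = TRUE), collapse = ""), "TAA")
    recoded <- synonymize(gene, 0.25)
    expect_false(gene == recoded)
    ctg <- seq_set("c", paste0(rnd_seq(300), recoded, rnd_seq(200)))
    h <- align_translated(ctg, seq_set("g", gene), 80)
    full <- h[h$gene_aa_start == 0 & h$gene_aa_end == h$gene_aa_len, ]
    expect_equal(nrow(full), 1)
    expect_equal(full$pct_id, 100)
})
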
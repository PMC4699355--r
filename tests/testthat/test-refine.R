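test_that("drop_short keeps contigs at exactly the minimum length", {
    set.seed(701)
    x <- seq_set(c("a", "b", "c"),
                 c(rnd_seq(1999), rnd_seq(2000), rnd_seq(5000)))
    out <- drop_short(x)
    expect_setequal(out$contigs$id, c("b", "c"))
    expect_equal(out$removed$reason, "too_short")
    expect_equal(nrow(drop_short(x[0, ])$contigs), 0)
    expect_equal(drop_short(x, 1)$contigs, x)
})

test_that("containment edges require identity, length fraction and linearity", {
    set.seed(702)
    B <- rnd_seq(20000)
    contigs <- seq_set(c("A", "B", "circ"),
                       c(substr(B, 3001, 8000), B, substr(B, 10001, 15000)),
                       circular = c(FALSE, FALSE, TRUE))
    hits <- align_all(contigs, contigs)
    M <- containment_graph(contigs, hits)
    expect_true(M["A", "B"])
    expect_false(M["circ", "B"]) # circular contigs are never contained
    expect_false(M["B", "A"])
})

test_that("transitive closure adds implied containments", {
    # constructed hits: A in B, B in C reported, A in C NOT reported
    contigs <- seq_set(c("A", "B", "C"),
                       c(strrep("ACGT", 500), strrep("ACGT", 1000),
                         strrep("ACGT", 1500)))
    mk <- function(a, b, alen) data.frame(
        ref_id = b, qry_id = a, ref_start = 0L, ref_end = alen,
        qry_start = 0L, qry_end = alen, strand = "+", pct_id = 100,
        aln_len = alen, ref_len = 6000L, qry_len = alen)
    hits <- rbind(mk("A", "B", 2000L), mk("B", "C", 4000L))
    M <- containment_graph(contigs, hits)
    expect_true(M["A", "C"]) # closure
    res <- resolve_containment(contigs, M)
    expect_equal(res$contigs$id, "C")
})

test_that("mutual-containment classes keep the longest member", {
    set.seed(703)
    s <- rnd_seq(10000)
    contigs <- seq_set(c("A", "B"), c(s, paste0(s, rnd_seq(200))))
    hits <- align_all(contigs, contigs)
    M <- containment_graph(contigs, hits)
    expect_true(M["A", "B"] && M["B", "A"])
    res <- resolve_containment(contigs, M)
    expect_equal(res$contigs$id, "B")
    expect_match(res$removed$reason, "equivalence_loser_to:B")
})

# Independent oracle: enumerate the refinement rules directly on a relation
# matrix (closure by fixpoint multiplication; classes by scanning).
brute_refine <- function(M, lens) {
    ids <- rownames(M)
    repeat {
        M2 <- M | (M %*% M > 0)
        diag(M2) <- FALSE
        if (identical(M2, M)) break
        M <- M2
    }
    alive <- ids
    mutual <- M & t(M)
    done <- character(0)
    for (a in ids) {
        if (a %in% done) next
        cls <- unique(c(a, ids[mutual[a, ]]))
        done <- c(done, cls)
        if (length(cls) > 1) {
            keep <- cls[order(-lens[cls], cls)][1]
            alive <- setdiff(alive, setdiff(cls, keep))
        }
    }
    # survivors: maximal elements among the remaining
    repeat {
        gone <- alive[vapply(alive, function(a)
            any(M[a, setdiff(alive, a)]), TRUE)]
        if (!length(gone)) break
        alive <- setdiff(alive, gone[1])
    }
    sort(alive)
}

test_that("containment resolution matches brute-force enumeration on random
           5-node relations", {
    set.seed(704)
    for (rep in 1:25) {
        n <- 5
        ids <- LETTERS[1:n]
        lens <- setNames(sample(2000:9000, n), ids)
        M <- matrix(runif(n * n) < 0.25, n, n, dimnames = list(ids, ids))
        diag(M) <- FALSE
        # close transitively as containment_graph would
        Mc <- M
        repeat {
            M2 <- Mc | (Mc %*% Mc > 0)
            diag(M2) <- FALSE
            if (identical(M2, Mc)) break
            Mc <- M2
        }
        contigs <- seq_set(ids, vapply(lens, function(l)
            strrep("A", l), ""))
        res <- resolve_containment(contigs, Mc)
        expect_equal(sort(res$contigs$id), brute_refine(M, lens))
    }
})

test_that("no surviving linear contig is contained in another survivor", {
    set.seed(705)
    G <- rnd_seq(30000)
    contigs <- seq_set(c("w", "x", "y", "z"),
                       c(G, substr(G, 1001, 9000), substr(G, 5001, 26000),
                         rnd_seq(4000)))
    res <- refine_contigs(contigs)
    surv <- res$contigs
    hits <- align_all(surv, surv)
    M <- containment_graph(surv, hits)
    expect_false(any(M))
    expect_setequal(surv$id, c("w", "z"))
})
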
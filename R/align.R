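#' Alignment parameters
#'
#' Controls for the built-in seed-chain-extend aligner, the stand-in for
#' nucmer-style contig matching at desk scale. Defaults mirror the matching
#' thresholds the pipeline's decision rules were written against: hits are kept
#' at >= 95 percent identity and anchor chains are bridged across gaps of up to
#' `breaklen` bases (the nucmer `-b` extension that carries alignments through
#' poorly aligned regions). `diagdiff` bounds the diagonal drift allowed
#' between adjacent anchors in one chain.
#'
#' @param min_pct_id minimum percent identity of a reported hit (default 95).
#' @param breaklen maximum gap, in bases on either sequence, bridged within
#'   one hit (default 500).
#' @param seed_k k-mer length for exact anchors (default 17; must be >= 8).
#' @param min_hit_len minimum alignment length of a reported hit (default 65).
#' @param diagdiff maximum diagonal difference between adjacent chained
#'   anchors (default 25).
#' @return A list of class `align_params`.
#' @export
align_params <- function(min_pct_id = 95, breaklen = 500, seed_k = 17,
                         min_hit_len = 65, diagdiff = 25) {
    stopifnot(min_pct_id > 0, min_pct_id <= 100, breaklen >= 0, seed_k >= 8,
              min_hit_len >= 1, diagdiff >= 0)
    structure(list(min_pct_id = min_pct_id, breaklen = breaklen,
                   seed_k = as.integer(seed_k), min_hit_len = min_hit_len,
                   diagdiff = diagdiff),
              class = "align_params")
}

empty_hits <- function() {
    data.frame(ref_id = character(), qry_id = character(),
               ref_start = integer(), ref_end = integer(),
               qry_start = integer(), qry_end = integer(),
               strand = character(), pct_id = numeric(),
               aln_len = integer(), ref_len = integer(), qry_len = integer(),
               stringsAsFactors = FALSE)
}

# Collapse exact anchor pairs into maximal same-diagonal runs ("segments").
# anchors: 2-col matrix (rpos, qpos), 0-based. A segment covers qry
# [q0, q1 + k) and ref [q0 + diag, q1 + diag + k).
anchor_segments <- function(anchors, k) {
    if (nrow(anchors) == 0)
        return(data.frame(diag = integer(), q0 = integer(), q1 = integer()))
    diag <- anchors[, 1] - anchors[, 2]
    o <- order(diag, anchors[, 2])
    diag <- diag[o]
    qpos <- anchors[o, 2]
    newrun <- c(TRUE, diff(diag) != 0 | diff(qpos) != 1)
    run <- cumsum(newrun)
    data.frame(diag = diag[newrun],
               q0 = qpos[newrun],
               q1 = qpos[cumsum(tabulate(run))])
}

# Greedy chaining of segments under diagonal-drift and gap constraints.
# Returns a list of integer vectors (row indices into segs).
chain_segments <- function(segs, k, breaklen, diagdiff) {
    n <- nrow(segs)
    if (n == 0) return(list())
    segs$r0 <- segs$q0 + segs$diag
    segs$r1 <- segs$q1 + segs$diag
    o <- order(segs$r0, segs$q0)
    segs <- segs[o, ]
    min_gap <- -(k + diagdiff)
    chains <- list()
    last_q <- integer(0); last_r <- integer(0); last_d <- integer(0)
    for (i in seq_len(n)) {
        r0 <- segs$r0[i]; q0 <- segs$q0[i]; d <- segs$diag[i]
        pick <- 0L
        if (length(chains)) {
            rgap <- r0 - last_r
            qgap <- q0 - last_q
            ok <- abs(d - last_d) <= diagdiff &
                rgap <= breaklen & qgap <= breaklen &
                rgap >= min_gap & qgap >= min_gap &
                q0 > last_q - k # monotone progress on the query
            if (any(ok)) {
                cand <- which(ok)
                pick <- cand[order(-last_r[cand], last_q[cand])][1]
            }
        }
        if (pick > 0L) {
            chains[[pick]] <- c(chains[[pick]], o[i])
            last_q[pick] <- segs$q1[i] + k
            last_r[pick] <- segs$r1[i] + k
            last_d[pick] <- d
        } else {
            chains[[length(chains) + 1L]] <- o[i]
            last_q <- c(last_q, segs$q1[i] + k)
            last_r <- c(last_r, segs$r1[i] + k)
            last_d <- c(last_d, d)
        }
    }
    chains
}

# Turn one chain into hit statistics on code vectors (forward orientation of
# both). Extends the chain span outward while bases match, then runs a banded
# global alignment across the span to obtain matches/columns.
hit_from_chain <- function(refc, qryc, segs, idx, k, pad = 8L) {
    sub <- segs[idx, , drop = FALSE]
    d <- sub$diag
    q_lo <- min(sub$q0); q_hi <- max(sub$q1) + k
    r_lo <- min(sub$q0 + sub$diag)
    r_hi <- max(sub$q1 + sub$diag) + k
    # maximal outward extension over exact matches
    while (r_lo > 0 && q_lo > 0 && refc[r_lo] >= 0 && refc[r_lo] == qryc[q_lo]) {
        r_lo <- r_lo - 1L; q_lo <- q_lo - 1L
    }
    nr <- length(refc); nq <- length(qryc)
    while (r_hi < nr && q_hi < nq && refc[r_hi + 1L] >= 0 &&
           refc[r_hi + 1L] == qryc[q_hi + 1L]) {
        r_hi <- r_hi + 1L; q_hi <- q_hi + 1L
    }
    off <- r_lo - q_lo
    dloc <- c(0L, (r_hi - r_lo) - (q_hi - q_lo), d - off)
    stats <- banded_stats_cpp(refc[(r_lo + 1):r_hi], qryc[(q_lo + 1):q_hi],
                              min(dloc) - pad, max(dloc) + pad)
    list(ref_start = r_lo, ref_end = r_hi, qry_start = q_lo, qry_end = q_hi,
         matches = stats[1], columns = stats[2],
         pct_id = 100 * stats[1] / stats[2],
         aln_len = max(r_hi - r_lo, q_hi - q_lo))
}

# Core pairwise driver: all hits of the queries against one reference code
# vector, one strand. Queries are streamed as one concatenated code vector
# with -1 separators (the rolling hash resets at negatives).
hits_vs_ref <- function(refc, qry_codes, qry_ids, params, alpha = 4L) {
    k <- params$seed_k
    lens <- vapply(qry_codes, length, 0L)
    concat <- vector("list", 2 * length(qry_codes))
    concat[seq(1, by = 2, length.out = length(qry_codes))] <- qry_codes
    concat[seq(2, by = 2, length.out = length(qry_codes))] <- list(-1L)
    concat <- unlist(concat, use.names = FALSE)
    offsets <- cumsum(c(0L, head(lens + 1L, -1L))) # start of each qry in concat
    anchors <- anchor_pairs_cpp(refc, concat, k, alpha)
    out <- vector("list", length(qry_codes))
    if (nrow(anchors) > 0) {
        qidx <- findInterval(anchors[, 2], offsets)
        anchors[, 2] <- anchors[, 2] - offsets[qidx]
        for (qi in unique(qidx)) {
            a <- anchors[qidx == qi, , drop = FALSE]
            segs <- anchor_segments(a, k)
            chains <- chain_segments(segs, k, params$breaklen, params$diagdiff)
            rows <- lapply(chains, function(ix)
                hit_from_chain(refc, qry_codes[[qi]], segs, ix, k))
            rows <- Filter(function(h) h$pct_id >= params$min_pct_id &&
                                       h$aln_len >= params$min_hit_len, rows)
            if (length(rows)) {
                out[[qi]] <- data.frame(
                    qry_id = qry_ids[qi],
                    ref_start = vapply(rows, `[[`, 0, "ref_start"),
                    ref_end = vapply(rows, `[[`, 0, "ref_end"),
                    qry_start = vapply(rows, `[[`, 0, "qry_start"),
                    qry_end = vapply(rows, `[[`, 0, "qry_end"),
                    pct_id = vapply(rows, `[[`, 0, "pct_id"),
                    aln_len = as.integer(vapply(rows, `[[`, 0, "aln_len")),
                    stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, out)
}

#' Align all queries against all references
#'
#' Seed-chain-extend local alignment on both strands: exact `seed_k`-mer
#' anchors (all occurrences, as with `nucmer --maxmatch`) are collapsed into
#' maximal exact segments, chained under the `diagdiff` constraint with gaps
#' up to `breaklen` bridged, extended outward, and scored by banded alignment.
#' Reverse-strand hits report the query interval on the query's forward strand
#' with `strand == "-"`.
#'
#' All coordinates are 0-based half-open. Percent identity is
#' matches / alignment columns * 100, unrounded.
#'
#' @param refs,qrys [seq_set()]s (non-empty).
#' @param params an [align_params()].
#' @return A hit data frame (columns `ref_id`, `qry_id`, `ref_start`,
#'   `ref_end`, `qry_start`, `qry_end`, `strand`, `pct_id`, `aln_len`,
#'   `ref_len`, `qry_len`).
#' @export
align_all <- function(refs, qrys, params = align_params()) {
    if (nrow(refs) == 0 || nrow(qrys) == 0) stop("empty input to align_all()")
    qcodes_f <- lapply(qrys$seq, dna_codes)
    qcodes_r <- lapply(revcomp(qrys$seq), dna_codes)
    qlens <- nchar(qrys$seq)
    res <- vector("list", 2 * nrow(refs))
    for (ri in seq_len(nrow(refs))) {
        refc <- dna_codes(refs$seq[ri])
        fwd <- hits_vs_ref(refc, qcodes_f, qrys$id, params)
        if (!is.null(fwd)) fwd$strand <- "+"
        rev <- hits_vs_ref(refc, qcodes_r, qrys$id, params)
        if (!is.null(rev)) {
            rev$strand <- "-"
            ql <- qlens[match(rev$qry_id, qrys$id)]
            qs <- ql - rev$qry_end
            qe <- ql - rev$qry_start
            rev$qry_start <- qs
            rev$qry_end <- qe
        }
        both <- rbind(fwd, rev)
        if (!is.null(both) && nrow(both)) {
            both$ref_id <- refs$id[ri]
            both$ref_len <- nchar(refs$seq[ri])
            both$qry_len <- qlens[match(both$qry_id, qrys$id)]
            res[[ri]] <- both
        }
    }
    hits <- do.call(rbind, res)
    if (is.null(hits) || nrow(hits) == 0) return(empty_hits())
    hits <- hits[, names(empty_hits())]
    hits <- hits[order(hits$ref_id, hits$qry_id, hits$strand,
                       hits$ref_start, hits$qry_start), ]
    rownames(hits) <- NULL
    hits
}

#' Filter hits by percent identity
#'
#' Keeps hits with `pct_id >= min_pct_id` (compared on the unrounded value),
#' preserving order; the analogue of `delta-filter -i`.
#'
#' @param hits a hit data frame.
#' @param min_pct_id percent identity threshold.
#' @return The retained subset.
#' @export
filter_hits <- function(hits, min_pct_id) {
    out <- hits[hits$pct_id >= min_pct_id, , drop = FALSE]
    rownames(out) <- NULL
    out
}

round_half_up <- function(x, digits) floor(x * 10^digits + 0.5) / 10^digits

#' Write and read coords-style hit tables
#'
#' Tab-delimited, `show-coords -dTlro`-like column order: ref_start, ref_end,
#' qry_start, qry_end, ref_len_aln, qry_len_aln, pct_id, ref_len, qry_len,
#' strand, ref_id, qry_id. Coordinates are 1-based inclusive; reverse-strand
#' hits are encoded with qry_start > qry_end, as MUMmer does. Percent identity
#' is rounded half-up to two decimals on write.
#'
#' @param hits a hit data frame.
#' @param path file to write or read.
#' @return `write_coords()` returns `path` invisibly; `read_coords()` returns
#'   a hit data frame.
#' @export
write_coords <- function(hits, path) {
    n <- nrow(hits)
    rs <- hits$ref_start + 1L; re <- hits$ref_end
    qs <- ifelse(hits$strand == "+", hits$qry_start + 1L, hits$qry_end)
    qe <- ifelse(hits$strand == "+", hits$qry_end, hits$qry_start + 1L)
    tab <- data.frame(rs, re, qs, qe,
                      ref_len_aln = hits$ref_end - hits$ref_start,
                      qry_len_aln = hits$qry_end - hits$qry_start,
                      pct_id = sprintf("%.2f", round_half_up(hits$pct_id, 2)),
                      ref_len = hits$ref_len, qry_len = hits$qry_len,
                      strand = hits$strand,
                      ref_id = hits$ref_id, qry_id = hits$qry_id)
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname write_coords
#' @export
read_coords <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0) return(empty_hits())
    tab <- tryCatch(
        read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(rep("integer", 6), "numeric",
                                  "integer", "integer", rep("character", 3))),
        error = function(e) stop("parse error in ", path, ": ",
                                 conditionMessage(e), call. = FALSE))
    if (ncol(tab) != 12) stop("parse error in ", path, ": expected 12 columns")
    bad <- which(!(tab[[10]] %in% c("+", "-")))
    if (length(bad)) stop("parse error in ", path, ": row ", bad[1],
                          ": invalid strand '", tab[bad[1], 10], "'")
    minus <- tab[[10]] == "-"
    data.frame(ref_id = tab[[11]], qry_id = tab[[12]],
               ref_start = tab[[1]] - 1L, ref_end = tab[[2]],
               qry_start = ifelse(minus, tab[[4]] - 1L, tab[[3]] - 1L),
               qry_end = ifelse(minus, tab[[3]], tab[[4]]),
               strand = tab[[10]], pct_id = tab[[7]],
               aln_len = pmax(tab[[5]], tab[[6]]),
               ref_len = tab[[8]], qry_len = tab[[9]],
               stringsAsFactors = FALSE)
}

translate_chr <- function(seq) {
    n <- 3 * (nchar(seq) %/% 3)
    if (n < 3) return("")
    suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAStringSet(substr(seq, 1, n)),
        if.fuzzy.codon = "solve", no.init.codon = TRUE)))
}

#' Translated search of genes against a contig
#'
#' Six-frame translation of the contig searched against translations of
#' nucleotide gene sequences (the PROmer-style protein-space search used to
#' locate anchor genes). Hits are reported in contig nucleotide coordinates on
#' the contig's forward strand; percent identity is measured on amino acids
#' and hits below `min_pct_id` are dropped. Gene coordinates (`gene_aa_start`,
#' `gene_aa_end`, `gene_aa_len`) are in amino acids.
#'
#' @param contig a single-record [seq_set()].
#' @param genes a [seq_set()] of nucleotide gene sequences (>= 1 codon each).
#' @param min_pct_id minimum amino-acid percent identity (default 80).
#' @return A data frame with one row per protein-space hit.
#' @export
align_translated <- function(contig, genes, min_pct_id = 80) {
    stopifnot(nrow(contig) == 1, nrow(genes) >= 1)
    if (any(nchar(genes$seq) < 3)) stop("gene shorter than one codon")
    L <- nchar(contig$seq)
    gene_aa <- vapply(genes$seq, translate_chr, "")
    gcodes <- lapply(gene_aa, aa_codes)
    params <- align_params(min_pct_id = min_pct_id, breaklen = 60,
                           seed_k = 8, min_hit_len = 10, diagdiff = 10)
    params$seed_k <- 5L # short anchors: protein space is information-dense
    out <- list()
    for (dir in c("+", "-")) {
        s <- if (dir == "+") contig$seq else revcomp(contig$seq)
        for (f in 0:2) {
            frame_aa <- translate_chr(substr(s, f + 1, L))
            if (nchar(frame_aa) < params$seed_k) next
            h <- hits_vs_ref(aa_codes(frame_aa), gcodes, genes$id, params,
                             alpha = 22L)
            if (is.null(h) || nrow(h) == 0) next
            nt_s <- f + 3L * h$ref_start
            nt_e <- f + 3L * h$ref_end
            if (dir == "-") { tmp <- nt_s; nt_s <- L - nt_e; nt_e <- L - tmp }
            out[[length(out) + 1L]] <- data.frame(
                gene_id = h$qry_id, contig_id = contig$id,
                ref_start = nt_s, ref_end = nt_e, strand = dir,
                pct_id = h$pct_id,
                gene_aa_start = h$qry_start, gene_aa_end = h$qry_end,
                gene_aa_len = nchar(gene_aa)[match(h$qry_id, genes$id)],
                frame = f, stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(gene_id = character(), contig_id = character(),
                          ref_start = integer(), ref_end = integer(),
                          strand = character(), pct_id = numeric(),
                          gene_aa_start = integer(), gene_aa_end = integer(),
                          gene_aa_len = integer(), frame = integer(),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res <- res[order(res$ref_start, match(res$gene_id, genes$id)), ]
    rownames(res) <- NULL
    res
}
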
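#' Local assembly parameters
#'
#' The greedy exact-overlap assembler tries each overlap length in `k_ladder`
#' in turn (longest first, to maximize contiguity) and stops at the first
#' ladder value that yields a unitig at least as long as the longest input
#' read. `min_overlap_id` is the percent identity required when verifying
#' candidate overlaps and single-read self-periods; at the default of 100 all
#' overlaps are exact, appropriate for corrected reads.
#'
#' @param k_ladder strictly decreasing overlap lengths
#'   (default 127, 121, 111, 101, 95, 91, 85, 81, 75, 71).
#' @param min_overlap_id percent identity for overlap verification
#'   (default 100).
#' @return A list of class `assemble_params`.
#' @export
assemble_params <- function(k_ladder = c(127L, 121L, 111L, 101L, 95L, 91L,
                                         85L, 81L, 75L, 71L),
                            min_overlap_id = 100) {
    k_ladder <- as.integer(k_ladder)
    stopifnot(length(k_ladder) >= 1, all(k_ladder >= 21),
              all(diff(k_ladder) < 0),
              min_overlap_id > 0, min_overlap_id <= 100)
    structure(list(k_ladder = k_ladder, min_overlap_id = min_overlap_id),
              class = "assemble_params")
}

# Percent identity of two equal-length strings (substitutions only).
ungapped_pct_id <- function(a, b) {
    ca <- utf8ToInt(a); cb <- utf8ToInt(b)
    100 * sum(ca == cb) / length(ca)
}

# Minimal self-period of a read: smallest p such that seq[1..n-p] matches
# seq[p+1..n] at >= min_id percent identity, with at least k bases of
# self-overlap as evidence. Exact case uses the KMP border. Returns the period
# or NA.
self_period <- function(seq, k, min_id = 100) {
    n <- nchar(seq)
    if (min_id >= 100) {
        border <- kmp_border_cpp(dna_codes(seq))
        if (border >= k) return(n - border)
        return(NA_integer_)
    }
    # tolerant mode: candidate periods from occurrences of the prefix k-mer
    pre <- substr(seq, 1, k)
    occ <- gregexpr(pre, seq, fixed = TRUE)[[1]]
    occ <- occ[occ > 1] - 1L # 0-based candidate periods
    for (p in occ) {
        if (n - p < k) next
        if (ungapped_pct_id(substr(seq, 1, n - p), substr(seq, p + 1, n)) >= min_id)
            return(p)
    }
    NA_integer_
}

#' Does a unitig path close into a circle?
#'
#' A multi-read path is circular when its terminal read has an exact (or
#' `min_overlap_id`-tolerant) suffix-prefix overlap of at least `k` bases onto
#' the initial read; a single read is circular when it spans its replicon more
#' than once, i.e. has a self-period leaving at least `k` bases of overlap.
#'
#' @param path_seqs character vector of read sequences in path order.
#' @param k overlap length in force.
#' @param min_overlap_id percent identity for overlap verification.
#' @return `TRUE` or `FALSE`.
#' @export
is_circular_closure <- function(path_seqs, k, min_overlap_id = 100) {
    stopifnot(length(path_seqs) >= 1)
    if (length(path_seqs) == 1)
        return(!is.na(self_period(path_seqs, k, min_overlap_id)))
    !is.na(best_overlap(path_seqs[length(path_seqs)], path_seqs[1], k,
                        min_overlap_id))
}

# Longest suffix(u)-prefix(v) overlap >= k at >= min_id identity, or NA.
best_overlap <- function(u, v, k, min_id = 100) {
    lu <- nchar(u); lv <- nchar(v)
    if (lu < k || lv < k) return(NA_integer_)
    occ <- gregexpr(substr(v, 1, k), u, fixed = TRUE)[[1]]
    if (occ[1] == -1) return(NA_integer_)
    for (p in occ - 1L) { # ascending p = descending overlap
        o <- lu - p
        if (o > lv) next # containment, not a proper overlap
        if (min_id >= 100) {
            if (substr(u, p + 1, lu) == substr(v, 1, o)) return(o)
        } else if (ungapped_pct_id(substr(u, p + 1, lu), substr(v, 1, o)) >= min_id) {
            return(o)
        }
    }
    NA_integer_
}

# One assembly attempt at a fixed overlap length k. nodes: data.frame with
# columns seq, src (source read id). Returns a list of units
# (seq, circular, n_reads).
try_assembly <- function(nodes, k, min_id) {
    n <- nrow(nodes)
    lens <- nchar(nodes$seq)
    # Pass 1: occurrences of every node's prefix k-mer in every node, via one
    # fixed-width dictionary sweep; classifies containments and overlaps.
    usable <- which(lens >= k)
    contained <- rep(FALSE, n)
    ov_from <- integer(0); ov_to <- integer(0); ov_len <- integer(0)
    if (length(usable) >= 1) {
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(
            substr(nodes$seq[usable], 1, k)))
        for (bi in seq_len(n)) {
            m <- Biostrings::matchPDict(pd, Biostrings::DNAString(nodes$seq[bi]))
            st <- Biostrings::startIndex(m)
            for (mi in seq_along(usable)) {
                ai <- usable[mi]
                if (ai == bi || nodes$src[ai] == nodes$src[bi]) next
                pos <- st[[mi]]
                if (is.null(pos)) next
                for (p in sort(pos) - 1L) { # 0-based
                    if (p + lens[ai] <= lens[bi]) { # containment candidate
                        if (contained[ai]) break
                        sub <- substr(nodes$seq[bi], p + 1, p + lens[ai])
                        if (min_id >= 100 && sub == nodes$seq[ai] ||
                            min_id < 100 && ungapped_pct_id(sub, nodes$seq[ai]) >= min_id) {
                            contained[ai] <- TRUE
                            break
                        }
                    } else { # overlap candidate: bi -> ai, length lens[bi] - p
                        o <- lens[bi] - p
                        suf <- substr(nodes$seq[bi], p + 1, lens[bi])
                        pre <- substr(nodes$seq[ai], 1, o)
                        if (min_id >= 100 && suf == pre ||
                            min_id < 100 && ungapped_pct_id(suf, pre) >= min_id) {
                            ov_from <- c(ov_from, bi)
                            ov_to <- c(ov_to, ai)
                            ov_len <- c(ov_len, o)
                            break # longest overlap for this pair found
                        }
                    }
                }
            }
        }
    }
    keep <- !contained
    live <- which(keep)
    sel <- ov_from %in% live & ov_to %in% live
    ov_from <- ov_from[sel]; ov_to <- ov_to[sel]; ov_len <- ov_len[sel]

    # Mutual-best edges; equal-best ties terminate extension (unitig rule).
    best_out <- rep(NA_integer_, n); best_out_len <- rep(NA_integer_, n)
    best_in <- rep(NA_integer_, n); best_in_len <- rep(NA_integer_, n)
    if (length(ov_from)) {
        for (e in order(-ov_len)) {
            u <- ov_from[e]; v <- ov_to[e]; o <- ov_len[e]
            if (is.na(best_out_len[u])) { best_out[u] <- v; best_out_len[u] <- o }
            else if (best_out_len[u] == o && best_out[u] != v) best_out[u] <- 0L
            if (is.na(best_in_len[v])) { best_in[v] <- u; best_in_len[v] <- o }
            else if (best_in_len[v] == o && best_in[v] != u) best_in[v] <- 0L
        }
    }
    succ <- rep(NA_integer_, n)
    for (u in live) {
        v <- best_out[u]
        if (!is.na(v) && v > 0L && !is.na(best_in[v]) && best_in[v] == u)
            succ[u] <- v
    }
    olap <- setNames(ov_len, paste(ov_from, ov_to))

    # Walk paths and cycles of the (<=1 in, <=1 out) successor graph.
    has_pred <- rep(FALSE, n); has_pred[succ[!is.na(succ)]] <- TRUE
    visited <- rep(FALSE, n)
    units <- list()
    walk <- function(start) {
        path <- integer(0)
        u <- start
        repeat {
            path <- c(path, u)
            visited[u] <<- TRUE
            v <- succ[u]
            if (is.na(v) || visited[v]) break
            u <- v
        }
        path
    }
    emit <- function(path, cyclic) {
        s <- nodes$seq[path[1]]
        if (length(path) > 1)
            for (i in 2:length(path)) {
                o <- olap[[paste(path[i - 1], path[i])]]
                s <- paste0(s, substr(nodes$seq[path[i]], o + 1, lens[path[i]]))
            }
        circ <- FALSE
        if (length(path) == 1) {
            p <- self_period(s, k, min_id)
            if (!is.na(p)) { s <- substr(s, 1, p); circ <- TRUE }
        } else if (cyclic) {
            o <- olap[[paste(path[length(path)], path[1])]]
            s <- substr(s, 1, nchar(s) - o)
            circ <- TRUE
        }
        units[[length(units) + 1L]] <<- list(seq = s, circular = circ,
                                             n_reads = length(path))
    }
    for (u in live[!has_pred[live]]) if (!visited[u]) emit(walk(u), FALSE)
    for (u in live) if (!visited[u]) { # remaining components are cycles
        path <- walk(u)
        cyclic <- !is.na(succ[path[length(path)]]) &&
            succ[path[length(path)]] == path[1]
        emit(path, cyclic)
    }
    units
}

same_unit <- function(a, b) {
    if (nchar(a$seq) != nchar(b$seq) || a$circular != b$circular) return(FALSE)
    if (!a$circular)
        return(a$seq == b$seq || a$seq == revcomp(b$seq))
    dd <- paste0(a$seq, a$seq)
    grepl(b$seq, dd, fixed = TRUE) || grepl(revcomp(b$seq), dd, fixed = TRUE)
}

#' Greedy overlap assembly of filtered reads into local units
#'
#' Builds an exact suffix-prefix overlap graph at the first ladder value,
#' removes contained reads, extends mutual-best unambiguous paths into
#' unitigs, and flags a unitig circular when its path closes on itself (or,
#' for a single read spanning its replicon more than once, when the read has a
#' self-period); circular units are emitted exactly once around. Both read
#' orientations are considered and strand-duplicate unitigs are removed. If no
#' unitig reaches the length of the longest read, the next ladder value is
#' tried.
#'
#' @param reads a read-record data frame from [filter_reads()] or any data
#'   frame/[seq_set()] with `id` and `seq` columns.
#' @param params an [assemble_params()].
#' @return A [seq_set()] of units with a `k_used` column; empty when no reads
#'   are given (never an error).
#' @export
assemble_units <- function(reads, params = assemble_params()) {
    if (nrow(reads) == 0) {
        out <- seq_set("placeholder", "A")[0, ]
        out$k_used <- integer(0)
        return(out)
    }
    seqs <- reads$seq[!duplicated(reads$seq)]
    ids <- reads$id[!duplicated(reads$seq)]
    nodes <- data.frame(seq = c(seqs, revcomp(seqs)), src = c(ids, ids),
                        stringsAsFactors = FALSE)
    max_read <- max(nchar(seqs))
    units <- list(); k_used <- params$k_ladder[1]
    for (k in params$k_ladder) {
        units <- try_assembly(nodes, k, params$min_overlap_id)
        k_used <- k
        if (!length(units)) next
        best <- max(vapply(units, function(u) nchar(u$seq), 0))
        # a unitig no longer than the longest read means nothing assembled
        # (unless there was only one read to begin with): step down the ladder
        if (best > max_read || length(seqs) == 1 ||
            any(vapply(units, `[[`, TRUE, "circular")))
            break
    }
    if (!length(units)) {
        out <- seq_set("placeholder", "A")[0, ]
        out$k_used <- integer(0)
        return(out)
    }
    # deterministic order, then strand-pair deduplication
    o <- order(-vapply(units, function(u) nchar(u$seq), 0),
               vapply(units, `[[`, "", "seq"))
    units <- units[o]
    keep <- rep(TRUE, length(units))
    for (i in seq_along(units)) {
        if (!keep[i]) next
        for (j in seq_along(units)) {
            if (j <= i || !keep[j]) next
            if (same_unit(units[[i]], units[[j]])) keep[j] <- FALSE
        }
    }
    units <- units[keep]
    out <- seq_set(paste0("unit.", seq_along(units)),
                   vapply(units, `[[`, "", "seq"),
                   circular = vapply(units, `[[`, TRUE, "circular"))
    out$k_used <- k_used
    out$n_reads <- vapply(units, `[[`, 0, "n_reads")
    out
}
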
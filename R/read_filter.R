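#' Read-filtering parameters
#'
#' Contigs of at least `length_cutoff` bases are "long": only reads mapping to
#' their first or last `end_window` bases are kept for local reassembly, and
#' reads spanning a window boundary are trimmed to the window side (kept only
#' if at least `min_trimmed_len` bases remain). Reads mapping to short contigs
#' and unmapped reads are kept whole.
#'
#' @param length_cutoff long/short contig boundary in bases (default 100000).
#' @param end_window window size at each contig end in bases (default 50000).
#' @param min_trimmed_len minimum length of a trimmed read (default 250).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(length_cutoff = 100000, end_window = 50000,
                          min_trimmed_len = 250) {
    stopifnot(length_cutoff >= 1, end_window >= 1, min_trimmed_len >= 1)
    structure(list(length_cutoff = length_cutoff, end_window = end_window,
                   min_trimmed_len = min_trimmed_len),
              class = "filter_params")
}

empty_read_records <- function() {
    data.frame(id = character(), seq = character(), source_read = character(),
               trimmed = logical(), origin = character(),
               stringsAsFactors = FALSE)
}

# Primary mapping per read: the hit maximizing aln_len * pct_id, ties broken
# toward (ref_id, ref_start) so multi-copy placements resolve deterministically
# to the left-most copy.
primary_hits <- function(hits) {
    if (nrow(hits) == 0) return(hits)
    score <- hits$aln_len * hits$pct_id
    o <- order(hits$qry_id, -score, hits$ref_id, hits$ref_start)
    h <- hits[o, ]
    h[!duplicated(h$qry_id), , drop = FALSE]
}

# Read-coordinate cut point corresponding to contig position `cpos`, by linear
# interpolation along the hit (exact when the alignment is gap-free).
cut_at <- function(h, cpos) {
    frac <- (cpos - h$ref_start) / (h$ref_end - h$ref_start)
    if (h$strand == "-") frac <- 1 - frac
    h$qry_start + round(frac * (h$qry_end - h$qry_start))
}

#' Filter and trim corrected reads near contig ends
#'
#' Selects the reads used for local reassembly. Each read is assigned to its
#' primary mapping (highest `aln_len * pct_id` hit); secondary hits are
#' ignored. On long contigs, reads wholly inside an end window are kept whole,
#' reads crossing a window boundary are trimmed to the window side (unaligned
#' overhangs beyond the contig end are kept, since they may bridge the
#' circle), and interior reads are discarded. Reads on short contigs and
#' unmapped reads are kept whole. A read crossing both windows of one contig
#' yields two records with `.left`/`.right` id suffixes.
#'
#' @param reads a [seq_set()] of corrected reads.
#' @param contigs a [seq_set()] of assembly contigs.
#' @param hits read-vs-contig hits (`ref` = contig, `qry` = read), e.g. from
#'   [align_all()].
#' @param params a [filter_params()].
#' @return A read-record data frame (columns `id`, `seq`, `source_read`,
#'   `trimmed`, `origin`).
#' @export
filter_reads <- function(reads, contigs, hits, params = filter_params()) {
    if (nrow(hits) > 0) {
        if (!all(hits$qry_id %in% reads$id)) stop("hit query ids not in reads")
        if (!all(hits$ref_id %in% contigs$id)) stop("hit reference ids not in contigs")
    }
    prim <- primary_hits(hits)
    clens <- seq_lengths(contigs)
    W <- params$end_window
    rec <- function(id, seq, src, trimmed, origin)
        data.frame(id = id, seq = seq, source_read = src, trimmed = trimmed,
                   origin = origin, stringsAsFactors = FALSE)
    out <- vector("list", nrow(reads))
    for (i in seq_len(nrow(reads))) {
        rid <- reads$id[i]
        rseq <- reads$seq[i]
        j <- match(rid, prim$qry_id)
        if (is.na(j)) {
            out[[i]] <- rec(rid, rseq, rid, FALSE, "unmapped")
            next
        }
        h <- prim[j, ]
        Lc <- clens[[h$ref_id]]
        if (Lc < params$length_cutoff) {
            out[[i]] <- rec(rid, rseq, rid, FALSE, "short_contig")
            next
        }
        ws <- Lc - W
        in_start <- h$ref_start < W
        in_end <- h$ref_end > ws
        if (in_start && h$ref_end <= W || in_end && h$ref_start >= ws) {
            out[[i]] <- rec(rid, rseq, rid, FALSE, "end_window")
            next
        }
        parts <- list()
        if (in_start) { # crosses the start-window boundary
            cut <- cut_at(h, W)
            part <- if (h$strand == "+") substr(rseq, 1, cut)
                    else substr(rseq, cut + 1, nchar(rseq))
            if (nchar(part) >= params$min_trimmed_len)
                parts$left <- part
        }
        if (in_end) { # crosses the end-window boundary
            cut <- cut_at(h, ws)
            part <- if (h$strand == "+") substr(rseq, cut + 1, nchar(rseq))
                    else substr(rseq, 1, cut)
            if (nchar(part) >= params$min_trimmed_len)
                parts$right <- part
        }
        if (length(parts) == 2) {
            out[[i]] <- rbind(
                rec(paste0(rid, ".left"), parts$left, rid, TRUE, "end_window"),
                rec(paste0(rid, ".right"), parts$right, rid, TRUE, "end_window"))
        } else if (length(parts) == 1) {
            out[[i]] <- rec(rid, parts[[1]], rid, TRUE, "end_window")
        } # else: interior read, or trimmed remnant too short -> discarded
    }
    res <- do.call(rbind, out)
    if (is.null(res)) return(empty_read_records())
    rownames(res) <- NULL
    res
}
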
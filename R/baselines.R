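#' Iterative end-trim circularization (optimized BLAST-style baseline)
#'
#' Repeatedly self-aligns the contig; whenever a same-strand hit pairs a
#' prefix interval with a suffix interval (both touching the respective
#' contig end, at or above the thresholds), the duplicated prefix is removed.
#' The shortest qualifying overlap is trimmed per iteration, so tandem
#' multi-copy contigs collapse one period at a time; iteration continues to a
#' fixpoint. The contig is flagged circular when at least one trim occurred.
#' Being a pure overlap method, it falsely circularizes linear contigs whose
#' ends carry the same repeat - the failure mode the read-based pipeline
#' guards against.
#'
#' @param contig a single-record [seq_set()].
#' @param min_overlap_len minimum prefix/suffix overlap trimmed (default
#'   2000, chosen to avoid spurious short-repeat trims).
#' @param min_pct_id minimum identity of the overlap hit (default 95).
#' @param end_tol maximum distance of the overlap from the contig ends
#'   (default 100).
#' @return A list: `contig` (trimmed, circular flag set), `circular`,
#'   `n_trims`.
#' @export
iterative_end_trim <- function(contig, min_overlap_len = 2000,
                               min_pct_id = 95, end_tol = 100) {
    stopifnot(nrow(contig) == 1)
    ap <- align_params(min_pct_id = min_pct_id,
                       min_hit_len = min(min_overlap_len, 65))
    n_trims <- 0L
    repeat {
        L <- nchar(contig$seq)
        h <- align_all(contig, contig, ap)
        trivial <- h$ref_start == h$qry_start & h$ref_end == h$qry_end &
            h$strand == "+"
        h <- h[!trivial & h$strand == "+", , drop = FALSE]
        # prefix-vs-suffix pairs: take (ref, qry) with ref at the start and
        # qry at the end (self-alignment reports both orders)
        sel <- h$ref_start <= end_tol & L - h$qry_end <= end_tol &
            h$ref_end <= h$qry_start &
            (h$ref_end - h$ref_start) >= min_overlap_len
        h <- h[sel, , drop = FALSE]
        if (nrow(h) == 0) break
        h <- h[order(h$ref_end - h$ref_start), , drop = FALSE] # shortest first
        contig$seq <- substr(contig$seq, h$ref_end[1] + 1, L)
        n_trims <- n_trims + 1L
    }
    contig$circular <- contig$circular | n_trims > 0L
    list(contig = contig, circular = contig$circular, n_trims = n_trims)
}

# Longest same-strand overlap hit pairing the end of `a` with the start of
# `b`, at the given thresholds; NULL when none qualifies.
end_start_overlap <- function(a, b, min_overlap_len, min_pct_id, end_tol) {
    ap <- align_params(min_pct_id = min_pct_id,
                       min_hit_len = min(min_overlap_len, 65))
    h <- align_all(a, b, ap)
    h <- h[h$strand == "+" &
           nchar(a$seq) - h$ref_end <= end_tol &
           h$qry_start <= end_tol &
           h$aln_len >= min_overlap_len, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    h[order(-h$aln_len, h$ref_start), ][1, ]
}

#' Split-and-merge circularization (optimized Minimus2-style baseline)
#'
#' Optionally pre-merges overlapping input contigs pairwise, then attempts
#' each contig in turn: the contig is broken in half and the two halves are
#' re-merged by detecting an overlap between the second half's end and the
#' first half's start (the original contig's end-start duplication). A single
#' merged result replaces the original, flagged circular; otherwise - or on
#' any internal failure - the original contig is retained. Each contig is
#' treated separately so that parts of different contigs are never merged.
#' Only the outermost duplication is recognized, so tandem multi-copy contigs
#' are not fully collapsed (the documented failure mode of this approach).
#'
#' @param contigs a [seq_set()].
#' @param min_overlap_len minimum merge overlap (default 2000).
#' @param min_pct_id minimum identity of the overlap (default 95).
#' @param end_tol maximum distance of the overlap from the relevant ends
#'   (default 100).
#' @param pre_merge pre-merge overlapping input contigs first (default TRUE).
#' @return A list: `contigs` (with circular flags) and a `report` data frame.
#' @export
split_merge_circularize <- function(contigs, min_overlap_len = 2000,
                                    min_pct_id = 95, end_tol = 100,
                                    pre_merge = TRUE) {
    if (pre_merge && nrow(contigs) > 1) {
        repeat {
            merged_any <- FALSE
            ids <- contigs$id
            for (i in seq_along(ids)) {
                for (j in seq_along(ids)) {
                    if (i == j) next
                    a <- contigs[contigs$id == ids[i], ]
                    b <- contigs[contigs$id == ids[j], ]
                    if (nrow(a) == 0 || nrow(b) == 0) next
                    h <- end_start_overlap(a, b, min_overlap_len, min_pct_id,
                                           end_tol)
                    if (is.null(h)) next
                    joined <- seq_set(paste0(a$id, "+", b$id),
                                      paste0(substr(a$seq, 1, h$ref_start),
                                             substr(b$seq, h$qry_start + 1,
                                                    nchar(b$seq))))
                    contigs <- contigs[!(contigs$id %in% c(a$id, b$id)), ]
                    contigs <- rbind(contigs, joined)
                    class(contigs) <- c("seq_set", "data.frame")
                    merged_any <- TRUE
                    break
                }
                if (merged_any) break
            }
            if (!merged_any) break
        }
    }
    report <- data.frame(contig = contigs$id, action = "unchanged",
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(contigs))) {
        res <- tryCatch({
            L <- nchar(contigs$seq[i])
            half <- L %/% 2
            h1 <- seq_set("half1", substr(contigs$seq[i], 1, half))
            h2 <- seq_set("half2", substr(contigs$seq[i], half + 1, L))
            ov <- end_start_overlap(h2, h1, min_overlap_len, min_pct_id,
                                    end_tol)
            if (is.null(ov)) NULL else
                paste0(substr(h2$seq, 1, ov$ref_start),
                       substr(h1$seq, ov$qry_start + 1, nchar(h1$seq)))
        }, error = function(e) NULL) # failure = keep the original
        if (!is.null(res)) {
            contigs$seq[i] <- res
            contigs$circular[i] <- TRUE
            report$action[i] <- "circularized"
        }
    }
    rownames(contigs) <- NULL
    list(contigs = contigs, report = report)
}
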
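#' Circularization parameters
#'
#' The replacement path requires unit-vs-contig hits covering at least
#' `min_contig_cov` of the contig, all to one circular unit, with one single
#' hit at least `min_unit_frac` of that unit's length. The end-join path
#' reuses the merge-stage end-distance criteria (`merge_p`).
#'
#' @param min_contig_cov fraction of the contig that must be covered
#'   (default 0.95).
#' @param min_unit_frac fraction of the unit one hit must span (default 0.95).
#' @param merge_p a [merge_params()] supplying the end-distance criteria and
#'   alignment thresholds.
#' @return A list of class `circularize_params`.
#' @export
circularize_params <- function(min_contig_cov = 0.95, min_unit_frac = 0.95,
                               merge_p = merge_params()) {
    stopifnot(min_contig_cov > 0, min_contig_cov <= 1,
              min_unit_frac > 0, min_unit_frac <= 1)
    structure(list(min_contig_cov = min_contig_cov,
                   min_unit_frac = min_unit_frac, merge_p = merge_p),
              class = "circularize_params")
}

# Total length of the union of [start, end) intervals.
interval_union_len <- function(start, end) {
    if (!length(start)) return(0L)
    o <- order(start)
    start <- start[o]; end <- end[o]
    tot <- 0L; cur_s <- start[1]; cur_e <- end[1]
    for (i in seq_along(start)[-1]) {
        if (start[i] > cur_e) {
            tot <- tot + (cur_e - cur_s)
            cur_s <- start[i]; cur_e <- end[i]
        } else cur_e <- max(cur_e, end[i])
    }
    tot + (cur_e - cur_s)
}

#' Circularize a contig by replacement with a circular unit
#'
#' If some circular unit's hits cover at least `min_contig_cov` of the contig,
#' and one of those hits spans at least `min_unit_frac` of the unit, the
#' contig is replaced by the unit's sequence (already stored exactly once
#' around). This is the path that collapses tandem multi-copy contigs of small
#' replicons to a single copy.
#'
#' @param contig a single-record [seq_set()].
#' @param units a [seq_set()] of local units (with `circular` flags).
#' @param hits contig-vs-unit hits (`ref` = contig, `qry` = unit).
#' @param params a [circularize_params()].
#' @return A list `(contig, action, unit_id)` where `action` is `"replaced"`
#'   or `"unchanged"`.
#' @export
circularize_by_replacement <- function(contig, units, hits,
                                       params = circularize_params()) {
    stopifnot(nrow(contig) == 1)
    clen <- nchar(contig$seq)
    h <- hits[hits$ref_id == contig$id, , drop = FALSE]
    best <- NULL
    for (ui in which(units$circular)) {
        uid <- units$id[ui]
        hu <- h[h$qry_id == uid, , drop = FALSE]
        if (nrow(hu) == 0) next
        cov <- interval_union_len(hu$ref_start, hu$ref_end) / clen
        ufrac <- max(hu$qry_end - hu$qry_start) / nchar(units$seq[ui])
        if (cov >= params$min_contig_cov && ufrac >= params$min_unit_frac &&
            (is.null(best) || cov > best$cov ||
             (cov == best$cov && uid < best$uid)))
            best <- list(uid = uid, ui = ui, cov = cov)
    }
    if (is.null(best))
        return(list(contig = contig, action = "unchanged", unit_id = NA_character_))
    new <- seq_set(contig$id, units$seq[best$ui], circular = TRUE)
    list(contig = new, action = "replaced", unit_id = best$uid)
}

#' Circularize a contig by joining its ends through one unit
#'
#' The longest hit near the contig start and the longest near the contig end
#' are identified under the merge-stage end-distance criteria; if they are the
#' same hit, the second longest substitutes on one side. The join is accepted
#' when both hits are to the same unit, no other hit of that unit to this
#' contig is longer than the smaller of the two and, after strand
#' normalization, the end-side hit touches the unit start, the start-side hit
#' touches the unit end, and the two unit intervals are strictly ordered
#' (nesting - the signature of repeat-flanked linear contigs - is rejected).
#' The output is the contig trimmed at both junctions with the unit's bridging
#' sequence closing the circle; duplicated junction sequence is removed and
#' missing junction sequence restored.
#'
#' @inheritParams circularize_by_replacement
#' @return A list `(contig, action, unit_id)` where `action` is `"end_joined"`
#'   or `"unchanged"`.
#' @export
circularize_by_end_join <- function(contig, units, hits,
                                    params = circularize_params()) {
    stopifnot(nrow(contig) == 1)
    mp <- params$merge_p
    clen <- nchar(contig$seq)
    unchanged <- list(contig = contig, action = "unchanged",
                      unit_id = NA_character_)
    h <- hits[hits$ref_id == contig$id, , drop = FALSE]
    if (nrow(h) < 2) return(unchanged)
    near_start <- which(h$ref_start <= mp$max_contig_end_dist)
    near_end <- which(clen - h$ref_end <= mp$max_contig_end_dist)
    ranked <- function(cand)
        cand[order(-h$aln_len[cand], h$qry_id[cand], h$ref_start[cand])]
    rs <- ranked(near_start); re <- ranked(near_end)
    if (!length(rs) || !length(re)) return(unchanged)
    # candidate (start, end) assignments; when the longest is shared, try the
    # second longest on either side
    cands <- list(c(rs[1], re[1]))
    if (rs[1] == re[1]) {
        cands <- list()
        if (length(re) > 1) cands <- c(cands, list(c(rs[1], re[2])))
        if (length(rs) > 1) cands <- c(cands, list(c(rs[2], re[1])))
    }
    for (cd in cands) {
        hs <- h[cd[1], ]; he <- h[cd[2], ]
        if (hs$qry_id != he$qry_id) next
        ulen <- nchar(get_seq(units, hs$qry_id))
        other <- h$aln_len[h$qry_id == hs$qry_id &
                           !(seq_len(nrow(h)) %in% cd)]
        if (length(other) && max(other) > min(hs$aln_len, he$aln_len)) next
        if (hs$strand != he$strand) next
        if (hs$strand == "-") {
            # normalize: flip the contig view so both hits read forward
            hs0 <- hs; he0 <- he
            hs <- flip_hit_ref(he0); he <- flip_hit_ref(hs0)
        }
        # end-side hit touches unit start; start-side hit touches unit end
        if (he$qry_start > mp$max_unit_end_dist) next
        if (ulen - hs$qry_end > mp$max_unit_end_dist) next
        # strict ordering on the unit: nested hits are rejected
        if (!(hs$qry_start > he$qry_start && hs$qry_end > he$qry_end)) next
        # junctions are placed at hit STARTS (always in aligned sequence, so
        # exact even when the duplicated tail carries indels): contig from the
        # start-side junction to the end-side hit's start, then the unit from
        # the end-side hit's start to the start-side hit's start
        if (he$ref_start < hs$ref_start) next
        useq <- get_seq(units, hs$qry_id)
        circ_unit <- units$circular[match(hs$qry_id, units$id)]
        if (circ_unit) {
            # the unit already holds the whole circle once around: emit it
            # rotated so the output starts where the contig does (exact, and
            # byte-identical on re-runs of clean inputs)
            newseq <- rotate(useq, hs$qry_start %% nchar(useq))
            if (h[cd[1], ]$strand == "-") newseq <- revcomp(newseq)
        } else {
            cseq <- contig$seq
            if (h[cd[1], ]$strand == "-") cseq <- revcomp(cseq)
            newseq <- paste0(substr(cseq, hs$ref_start + 1, he$ref_start),
                             substr(useq, he$qry_start + 1, hs$qry_start))
            if (h[cd[1], ]$strand == "-") newseq <- revcomp(newseq)
        }
        if (nchar(newseq) == 0) next
        new <- seq_set(contig$id, newseq, circular = TRUE)
        return(list(contig = new, action = "end_joined", unit_id = hs$qry_id))
    }
    unchanged
}

#' Circularize every contig of an assembly
#'
#' Attempts, for each contig not already flagged circular, replacement by a
#' circular unit first and end-joining second; contigs where neither path
#' fires pass through byte-identical. Hits are computed here (contig vs unit)
#' at the merge-stage thresholds.
#'
#' @param contigs,units [seq_set()]s.
#' @param params a [circularize_params()].
#' @param hits optional precomputed contig-vs-unit hits.
#' @return A list: `contigs` (possibly modified, circular flags set) and a
#'   per-contig `report` (contig, action, unit_id, length in/out).
#' @export
circularize_contigs <- function(contigs, units,
                                params = circularize_params(), hits = NULL) {
    mp <- params$merge_p
    if (is.null(hits)) {
        hits <- if (nrow(units) == 0) empty_hits() else
            align_all(contigs, units,
                      align_params(min_pct_id = mp$min_pct_id,
                                   breaklen = mp$breaklen))
    }
    report <- data.frame(contig = contigs$id, action = "unchanged",
                         unit_id = NA_character_,
                         len_in = nchar(contigs$seq),
                         len_out = nchar(contigs$seq),
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(contigs))) {
        if (contigs$circular[i]) { report$action[i] <- "already_circular"; next }
        if (nrow(units) == 0) next
        res <- circularize_by_replacement(contigs[i, ], units, hits, params)
        if (res$action == "unchanged")
            res <- circularize_by_end_join(contigs[i, ], units, hits, params)
        if (res$action != "unchanged") {
            contigs$seq[i] <- res$contig$seq
            contigs$circular[i] <- TRUE
            report$action[i] <- res$action
            report$unit_id[i] <- res$unit_id
            report$len_out[i] <- nchar(res$contig$seq)
        }
    }
    list(contigs = contigs, report = report)
}
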
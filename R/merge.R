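#' Contig-merging parameters
#'
#' A local unit can merge two assembly contigs when its two end matches are at
#' least `min_match_len` bases long, start or end within `max_unit_end_dist`
#' bases of the respective unit end, land within `max_contig_end_dist` bases
#' of a contig end (more tolerance on the contig side, whose ends are often
#' low quality), touch two different contigs, and no other hit of that unit is
#' longer than the smaller of the two. Alignments feeding these rules are run
#' at `min_pct_id` / `breaklen`.
#'
#' @param min_match_len minimum end-match length in bases (default 4000).
#' @param max_unit_end_dist maximum distance of a match from the unit end
#'   (default 1000).
#' @param max_contig_end_dist maximum distance of a match from the contig end
#'   (default 15000).
#' @param min_pct_id percent identity for unit-vs-contig alignment
#'   (default 95; 85 for nanopore-grade data).
#' @param breaklen aligner gap-bridging distance (default 500; 1000 for
#'   nanopore-grade data).
#' @param max_iterations safety bound on filter/assemble/merge rounds
#'   (default 10).
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(min_match_len = 4000, max_unit_end_dist = 1000,
                         max_contig_end_dist = 15000, min_pct_id = 95,
                         breaklen = 500, max_iterations = 10) {
    stopifnot(min_match_len > 0, max_unit_end_dist > 0,
              max_contig_end_dist > 0, min_pct_id > 0, min_pct_id <= 100,
              breaklen >= 0, max_iterations >= 1)
    structure(list(min_match_len = min_match_len,
                   max_unit_end_dist = max_unit_end_dist,
                   max_contig_end_dist = max_contig_end_dist,
                   min_pct_id = min_pct_id, breaklen = breaklen,
                   max_iterations = max_iterations),
              class = "merge_params")
}

# Mirror a hit's contig-side interval and strand so the hit reads as "+" on a
# reverse-complemented contig.
flip_hit_ref <- function(h) {
    rs <- h$ref_len - h$ref_end
    h$ref_end <- h$ref_len - h$ref_start
    h$ref_start <- rs
    h$strand <- if (h$strand == "+") "-" else "+"
    h
}

no_decision <- function() {
    data.frame(unit_id = character(), left_contig_id = character(),
               right_contig_id = character(), accepted = logical(),
               reason = character(),
               left_ref_start = integer(), left_ref_end = integer(),
               left_flip = logical(), left_unit_start = integer(),
               left_unit_end = integer(),
               right_ref_start = integer(), right_ref_end = integer(),
               right_flip = logical(), right_unit_start = integer(),
               right_unit_end = integer(), stringsAsFactors = FALSE)
}

#' Propose contig merges mediated by local units
#'
#' For each unit, the longest hit starting within `max_unit_end_dist` of the
#' unit start and the longest ending within `max_unit_end_dist` of the unit
#' end are identified (`qry` = unit, `ref` = contig). The pair is accepted
#' when both exist, are at least `min_match_len` long, touch different
#' contigs, no other hit of the unit is strictly longer than the smaller of
#' the two, and orientations/positions admit a consistent join: after
#' orienting each contig so its hit is forward, the unit must walk off the end
#' of the left contig and into the start of the right one.
#'
#' @param units a [seq_set()] of local units.
#' @param contigs a [seq_set()] of assembly contigs.
#' @param hits unit-vs-contig hits (`ref` = contig, `qry` = unit).
#' @param params a [merge_params()].
#' @return A merge-decision data frame; accepted rows carry the junction
#'   coordinates consumed by [apply_merge()].
#' @export
propose_merges <- function(units, contigs, hits, params = merge_params()) {
    out <- no_decision()
    for (ui in seq_len(nrow(units))) {
        uid <- units$id[ui]
        ulen <- nchar(units$seq[ui])
        h <- hits[hits$qry_id == uid, , drop = FALSE]
        if (nrow(h) == 0) next
        dec <- data.frame(unit_id = uid, left_contig_id = NA_character_,
                          right_contig_id = NA_character_, accepted = FALSE,
                          reason = "", left_ref_start = NA_integer_,
                          left_ref_end = NA_integer_, left_flip = NA,
                          left_unit_start = NA_integer_,
                          left_unit_end = NA_integer_,
                          right_ref_start = NA_integer_,
                          right_ref_end = NA_integer_, right_flip = NA,
                          right_unit_start = NA_integer_,
                          right_unit_end = NA_integer_,
                          stringsAsFactors = FALSE)
        reject <- function(why) { dec$reason <- why; rbind(out, dec) }
        near_start <- which(h$qry_start <= params$max_unit_end_dist)
        near_end <- which(ulen - h$qry_end <= params$max_unit_end_dist)
        pick <- function(cand) {
            if (!length(cand)) return(NA_integer_)
            cand[order(-h$aln_len[cand], h$ref_id[cand], h$ref_start[cand])][1]
        }
        i1 <- pick(near_start); i2 <- pick(near_end)
        if (is.na(i1) || is.na(i2)) { out <- reject("no_end_match"); next }
        if (i1 == i2) { out <- reject("single_end_match"); next }
        h1 <- h[i1, ]; h2 <- h[i2, ]
        dec$left_contig_id <- h1$ref_id; dec$right_contig_id <- h2$ref_id
        if (h1$ref_id == h2$ref_id) { out <- reject("same_contig"); next }
        if (min(h1$aln_len, h2$aln_len) < params$min_match_len) {
            out <- reject("min_match_len"); next
        }
        other <- h$aln_len[-c(i1, i2)]
        if (length(other) && max(other) > min(h1$aln_len, h2$aln_len)) {
            out <- reject("longer_hit_elsewhere"); next
        }
        # orient both contigs so their hit is forward
        f1 <- h1$strand == "-"; if (f1) h1 <- flip_hit_ref(h1)
        f2 <- h2$strand == "-"; if (f2) h2 <- flip_hit_ref(h2)
        # unit start-side hit must sit at the LEFT contig's end, unit end-side
        # hit at the RIGHT contig's start
        if (h1$ref_len - h1$ref_end > params$max_contig_end_dist ||
            h2$ref_start > params$max_contig_end_dist) {
            out <- reject("contig_end_dist"); next
        }
        if (!(h2$qry_start > h1$qry_start && h2$qry_end > h1$qry_end)) {
            out <- reject("inconsistent_geometry"); next
        }
        dec$accepted <- TRUE; dec$reason <- "ok"
        dec$left_ref_start <- h1$ref_start; dec$left_ref_end <- h1$ref_end
        dec$left_flip <- f1
        dec$left_unit_start <- h1$qry_start; dec$left_unit_end <- h1$qry_end
        dec$right_ref_start <- h2$ref_start; dec$right_ref_end <- h2$ref_end
        dec$right_flip <- f2
        dec$right_unit_start <- h2$qry_start; dec$right_unit_end <- h2$qry_end
        out <- rbind(out, dec)
    }
    rownames(out) <- NULL
    out
}

#' Apply one accepted merge decision
#'
#' Builds the merged contig as: left contig up to its junction, the unit's
#' sequence from the start-side match through the end-side match (local
#' reassembly is trusted across low-quality contig ends), then the right
#' contig from its junction. Contigs are reverse-complemented first when their
#' hit was on the minus strand. The merged id records both parents.
#'
#' @param decision one accepted row from [propose_merges()].
#' @param contigs the current [seq_set()] of contigs.
#' @param units the [seq_set()] of local units.
#' @return A single-record [seq_set()] with the merged contig.
#' @export
apply_merge <- function(decision, contigs, units) {
    stopifnot(nrow(decision) == 1, isTRUE(decision$accepted))
    left <- get_seq(contigs, decision$left_contig_id)
    right <- get_seq(contigs, decision$right_contig_id)
    if (decision$left_flip) left <- revcomp(left)
    if (decision$right_flip) right <- revcomp(right)
    useq <- get_seq(units, decision$unit_id)
    merged <- paste0(substr(left, 1, decision$left_ref_start),
                     substr(useq, decision$left_unit_start + 1,
                            decision$right_unit_end),
                     substr(right, decision$right_ref_end + 1, nchar(right)))
    seq_set(paste0(decision$left_contig_id, "+", decision$right_contig_id),
            merged)
}

#' Iterate read filtering, local assembly and merging to a fixpoint
#'
#' Runs the merge loop: map reads to the current assembly, filter them to
#' contig ends, assemble local units, propose and apply merges; after each
#' round the reads are remapped to the new assembly. Stops when a round
#' applies no merge or `max_iterations` is reached. When several accepted
#' decisions touch the same contig in one round, the one with the largest
#' combined match length wins and the others wait for the next round.
#'
#' @param contigs,reads [seq_set()]s.
#' @param filter_p,assemble_p,merge_p stage parameter objects.
#' @param align_p alignment parameters for read mapping (unit-vs-contig
#'   alignments always use the merge thresholds).
#' @return A list: final `contigs`, last round's `units` and unit-vs-contig
#'   `hits`, per-round `log`, all merge `decisions`, and `n_iterations`.
#' @export
merge_to_fixpoint <- function(contigs, reads,
                              filter_p = filter_params(),
                              assemble_p = assemble_params(),
                              merge_p = merge_params(),
                              align_p = align_params()) {
    unit_align_p <- align_params(min_pct_id = merge_p$min_pct_id,
                                 breaklen = merge_p$breaklen,
                                 seed_k = align_p$seed_k,
                                 min_hit_len = align_p$min_hit_len,
                                 diagdiff = align_p$diagdiff)
    log <- data.frame(iteration = integer(), merges_applied = integer(),
                      n_contigs = integer(), n_units = integer())
    all_dec <- no_decision()
    units <- NULL; unit_hits <- NULL
    for (it in seq_len(merge_p$max_iterations)) {
        read_hits <- align_all(contigs, reads, align_p)
        filtered <- filter_reads(reads, contigs, read_hits, filter_p)
        units <- assemble_units(filtered, assemble_p)
        if (nrow(units) == 0) {
            unit_hits <- empty_hits()
            log <- rbind(log, data.frame(iteration = it, merges_applied = 0L,
                                         n_contigs = nrow(contigs),
                                         n_units = 0L))
            break
        }
        unit_hits <- align_all(contigs, units, unit_align_p)
        dec <- propose_merges(units, contigs, unit_hits, merge_p)
        all_dec <- rbind(all_dec, dec)
        acc <- dec[dec$accepted, , drop = FALSE]
        applied <- 0L
        if (nrow(acc)) {
            comb <- (acc$left_ref_end - acc$left_ref_start) +
                (acc$right_ref_end - acc$right_ref_start)
            acc <- acc[order(-comb, acc$unit_id), , drop = FALSE]
            used <- character(0)
            for (di in seq_len(nrow(acc))) {
                d <- acc[di, ]
                if (d$left_contig_id %in% used || d$right_contig_id %in% used)
                    next
                merged <- apply_merge(d, contigs, units)
                contigs <- contigs[!(contigs$id %in%
                                     c(d$left_contig_id, d$right_contig_id)), ]
                contigs <- rbind(contigs, merged)
                class(contigs) <- c("seq_set", "data.frame")
                used <- c(used, d$left_contig_id, d$right_contig_id)
                applied <- applied + 1L
            }
        }
        log <- rbind(log, data.frame(iteration = it, merges_applied = applied,
                                     n_contigs = nrow(contigs),
                                     n_units = nrow(units)))
        if (applied == 0L) break
    }
    rownames(contigs) <- NULL
    list(contigs = contigs, units = units, hits = unit_hits, log = log,
         decisions = all_dec, n_iterations = nrow(log))
}
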
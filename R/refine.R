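#' Refinement parameters
#'
#' @param min_contig_len contigs shorter than this are discarded
#'   (default 2000).
#' @param containment_min_id percent identity of a containing alignment
#'   (default 95).
#' @param containment_min_frac fraction of the contained contig one alignment
#'   must span (default 0.95).
#' @return A list of class `refine_params`.
#' @export
refine_params <- function(min_contig_len = 2000, containment_min_id = 95,
                          containment_min_frac = 0.95) {
    stopifnot(min_contig_len > 0, containment_min_id > 0,
              containment_min_id <= 100, containment_min_frac > 0,
              containment_min_frac <= 1)
    structure(list(min_contig_len = min_contig_len,
                   containment_min_id = containment_min_id,
                   containment_min_frac = containment_min_frac),
              class = "refine_params")
}

#' Drop short contigs
#'
#' @param contigs a [seq_set()].
#' @param min_contig_len minimum retained length in bases (contigs of exactly
#'   this length are kept).
#' @return A list: `contigs` (the survivors) and `removed` (a log data frame).
#' @export
drop_short <- function(contigs, min_contig_len = 2000) {
    short <- nchar(contigs$seq) < min_contig_len
    removed <- data.frame(contig = contigs$id[short],
                          reason = rep("too_short", sum(short)),
                          stringsAsFactors = FALSE)
    out <- contigs[!short, , drop = FALSE]
    rownames(out) <- NULL
    list(contigs = out, removed = removed)
}

#' Containment relation between contigs
#'
#' Contig A is contained in contig B when A has not been identified as
#' circular and a single self-alignment hit of A against B has identity at
#' least `containment_min_id` and length at least `containment_min_frac` of
#' A's length. The relation is closed transitively.
#'
#' @param contigs a [seq_set()].
#' @param self_hits hits from aligning the assembly to itself (`ref` and `qry`
#'   both contigs); identity hits of a contig to itself are ignored.
#' @param params a [refine_params()].
#' @return A logical matrix `M` with `M[A, B]` meaning A contained in B.
#' @export
containment_graph <- function(contigs, self_hits, params = refine_params()) {
    n <- nrow(contigs)
    M <- matrix(FALSE, n, n, dimnames = list(contigs$id, contigs$id))
    h <- self_hits
    trivial <- h$ref_id == h$qry_id & h$strand == "+" &
        h$ref_start == h$qry_start & h$ref_end == h$qry_end
    h <- h[!trivial & h$ref_id != h$qry_id, , drop = FALSE]
    alen <- setNames(nchar(contigs$seq), contigs$id)
    for (i in seq_len(nrow(h))) {
        A <- h$qry_id[i]; B <- h$ref_id[i]
        if (!(A %in% contigs$id) || !(B %in% contigs$id)) next
        if (contigs$circular[match(A, contigs$id)]) next
        if (h$pct_id[i] >= params$containment_min_id &&
            (h$qry_end[i] - h$qry_start[i]) >=
                params$containment_min_frac * alen[[A]])
            M[A, B] <- TRUE
    }
    # transitive closure (assemblies are small; Warshall is fine)
    for (k in seq_len(n)) for (a in seq_len(n))
        if (M[a, k]) M[a, ] <- M[a, ] | M[k, ]
    diag(M) <- FALSE
    M
}

#' Remove contained contigs
#'
#' Mutual-containment equivalence classes are collapsed to their longest
#' member (ties to the lexicographically smallest id); every remaining contig
#' contained in a surviving contig is then removed.
#'
#' @param contigs a [seq_set()].
#' @param relation transitively closed containment matrix from
#'   [containment_graph()].
#' @return A list: `contigs` (survivors) and `removed` (a log data frame with
#'   reasons).
#' @export
resolve_containment <- function(contigs, relation) {
    ids <- contigs$id
    lens <- setNames(nchar(contigs$seq), ids)
    removed <- data.frame(contig = character(), reason = character(),
                          stringsAsFactors = FALSE)
    drop <- character(0)
    # mutual classes
    mutual <- relation & t(relation)
    seen <- character(0)
    for (a in ids) {
        if (a %in% seen) next
        cls <- c(a, ids[mutual[a, ids]])
        seen <- c(seen, cls)
        if (length(cls) < 2) next
        winner <- cls[order(-lens[cls], cls)][1]
        losers <- setdiff(cls, winner)
        drop <- c(drop, losers)
        removed <- rbind(removed, data.frame(
            contig = losers, reason = paste0("equivalence_loser_to:", winner),
            stringsAsFactors = FALSE))
    }
    surviving <- setdiff(ids, drop)
    repeat {
        again <- FALSE
        for (a in surviving) {
            hosts <- surviving[relation[a, surviving] & surviving != a]
            if (length(hosts)) {
                surviving <- setdiff(surviving, a)
                removed <- rbind(removed, data.frame(
                    contig = a, reason = paste0("contained_in:", hosts[1]),
                    stringsAsFactors = FALSE))
                again <- TRUE
                break
            }
        }
        if (!again) break
    }
    out <- contigs[contigs$id %in% surviving, , drop = FALSE]
    rownames(out) <- NULL
    list(contigs = out, removed = removed)
}

#' Refine an assembly
#'
#' Drops short contigs, then removes redundant contained contigs using a
#' self-alignment of the assembly at the containment thresholds.
#'
#' @param contigs a [seq_set()].
#' @param params a [refine_params()].
#' @param align_p alignment parameters for the self-alignment.
#' @return A list: `contigs` and the combined `removed` log.
#' @export
refine_contigs <- function(contigs, params = refine_params(),
                           align_p = align_params(
                               min_pct_id = params$containment_min_id)) {
    step1 <- drop_short(contigs, params$min_contig_len)
    contigs <- step1$contigs
    removed <- step1$removed
    if (nrow(contigs) > 1) {
        self_hits <- align_all(contigs, contigs, align_p)
        M <- containment_graph(contigs, self_hits, params)
        step2 <- resolve_containment(contigs, M)
        contigs <- step2$contigs
        removed <- rbind(removed, step2$removed)
    }
    list(contigs = contigs, removed = removed)
}
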
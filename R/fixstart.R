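#' Find an anchor gene on a circular contig
#'
#' Translated search of the gene set against the contig; among hits spanning
#' the full translated length of a gene at or above `min_pct_id` amino-acid
#' identity, the first in (contig position, gene file order) is returned.
#'
#' @param contig a single-record [seq_set()] (circular).
#' @param genes a [seq_set()] of nucleotide gene sequences (e.g. dnaA
#'   homologs).
#' @param min_pct_id minimum amino-acid percent identity (default 80).
#' @return A one-row data frame (`gene_id`, `contig_id`, `contig_start`,
#'   `strand`, `pct_id`, `spans_full_gene`) or `NULL` when no full-length
#'   match exists.
#' @export
find_anchor <- function(contig, genes, min_pct_id = 80) {
    # the contig is circular: extend it past the origin so genes straddling
    # the linearization point are still seen at full length
    L <- nchar(contig$seq)
    pad <- min(L, max(nchar(genes$seq)) + 3L)
    ext <- contig
    ext$seq <- paste0(contig$seq, substr(contig$seq, 1, pad))
    h <- align_translated(ext, genes, min_pct_id)
    full <- h[h$gene_aa_start == 0 & h$gene_aa_end == h$gene_aa_len, ,
              drop = FALSE]
    if (nrow(full) == 0) return(NULL)
    full$contig_start <- ifelse(full$strand == "+", full$ref_start,
                                full$ref_end) %% L # first base of the gene
    full <- full[!duplicated(full[, c("gene_id", "contig_start", "strand")]), ,
                 drop = FALSE]
    full <- full[order(full$ref_start %% L, match(full$gene_id, genes$id)), ]
    f <- full[1, ]
    data.frame(gene_id = f$gene_id, contig_id = f$contig_id,
               contig_start = f$contig_start, strand = f$strand,
               pct_id = f$pct_id, spans_full_gene = TRUE,
               ref_start = f$ref_start, ref_end = f$ref_end,
               stringsAsFactors = FALSE)
}

#' Rotate a circular contig to start at an anchor gene
#'
#' Reverse-complements the contig first when the gene lies on the minus
#' strand, then rotates so the gene's first base becomes position 0 on the
#' forward strand.
#'
#' @param contig a single-record [seq_set()] (circular).
#' @param match a gene match from [find_anchor()].
#' @return The rotated [seq_set()].
#' @export
rotate_to_anchor <- function(contig, match) {
    stopifnot(nrow(contig) == 1)
    s <- contig$seq
    L <- nchar(s)
    off <- match$contig_start
    if (match$strand == "-") {
        s <- revcomp(s)
        off <- L - match$contig_start # gene start in flipped coordinates
    }
    contig$seq <- rotate(s, off %% L)
    contig
}

#' Find open reading frames
#'
#' Minimal ORF caller used for the fallback start: on both strands, an ORF
#' runs from the first start codon (ATG/GTG/TTG) after a stop to the next
#' in-frame stop (inclusive), standard code, minimum `min_len` nucleotides.
#' ORFs touching either contig end are not called.
#'
#' @param seq a single sequence string.
#' @param min_len minimum ORF length in nucleotides, stop included
#'   (default 300).
#' @return A data frame with 0-based forward-strand coordinates (`start`,
#'   `end`), `strand`, and `gene_start` (the first transcribed base in
#'   forward coordinates).
#' @export
find_orfs <- function(seq, min_len = 300) {
    L <- nchar(seq)
    starts <- c("ATG", "GTG", "TTG"); stops <- c("TAA", "TAG", "TGA")
    scan <- function(s) {
        out <- list()
        for (f in 0:2) {
            n_cod <- (nchar(s) - f) %/% 3
            if (n_cod < 2) next
            codons <- substring(s, f + 1 + 3 * (0:(n_cod - 1)),
                                f + 3 * (1:n_cod))
            stop_at <- which(codons %in% stops)
            prev <- 0L
            for (sa in stop_at) {
                cand <- which(codons[(prev + 1):(sa - 1)] %in% starts)
                if (length(cand) && sa > prev + 1) {
                    beg <- prev + cand[1]
                    if (3 * (sa - beg + 1) >= min_len)
                        out[[length(out) + 1L]] <-
                            c(f + 3L * (beg - 1L), f + 3L * sa)
                }
                prev <- sa
            }
        }
        out
    }
    rows <- list()
    for (o in scan(seq))
        rows[[length(rows) + 1L]] <- data.frame(
            start = o[1], end = o[2], strand = "+", gene_start = o[1])
    for (o in scan(revcomp(seq)))
        rows[[length(rows) + 1L]] <- data.frame(
            start = L - o[2], end = L - o[1], strand = "-",
            gene_start = L - o[1] - 1L)
    if (!length(rows))
        return(data.frame(start = integer(), end = integer(),
                          strand = character(), gene_start = integer(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out <- out[out$start > 0 & out$end < L, , drop = FALSE] # strictly inside
    rownames(out) <- NULL
    out
}

#' Fallback rotation offset: the predicted gene nearest the contig middle
#'
#' Used when no anchor gene matches: ORFs strictly inside the contig are
#' predicted and the one whose (biological) start is nearest `len/2` is
#' chosen; ties prefer the forward strand, then the lower coordinate.
#'
#' @param contig a single-record [seq_set()] (circular).
#' @param min_orf_len minimum ORF length in nucleotides (default 300).
#' @return A list `(offset, strand)` or `NULL` when no ORF is found.
#' @export
fallback_middle_gene <- function(contig, min_orf_len = 300) {
    stopifnot(nrow(contig) == 1)
    orfs <- find_orfs(contig$seq, min_orf_len)
    if (nrow(orfs) == 0) return(NULL)
    L <- nchar(contig$seq)
    d <- abs(orfs$gene_start - L / 2)
    o <- order(d, orfs$strand != "+", orfs$gene_start)
    list(offset = orfs$gene_start[o[1]], strand = orfs$strand[o[1]])
}

#' Rotate all circular contigs to a standard start
#'
#' Each circular contig is searched for an anchor gene (dnaA homologs, by
#' default the synthetic set shipped with the package) and rotated to start
#' with it on the forward strand; when no full-length match is found, the
#' start of the predicted gene nearest the contig middle is used. Linear
#' contigs are never rotated.
#'
#' @param contigs a [seq_set()].
#' @param genes a [seq_set()] of anchor genes, or `NULL` to go straight to the
#'   middle-gene fallback.
#' @param min_pct_id minimum amino-acid identity for anchor matches
#'   (default 80).
#' @return A list: rotated `contigs` and a `report` data frame (contig,
#'   method, offset, strand_flipped).
#' @export
fix_starts <- function(contigs, genes = NULL, min_pct_id = 80) {
    report <- data.frame(contig = contigs$id, method = "none",
                         offset = NA_integer_, strand_flipped = FALSE,
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(contigs))) {
        if (!contigs$circular[i]) { report$method[i] <- "not_circular"; next }
        ctg <- contigs[i, ]
        anchor <- if (!is.null(genes) && nrow(genes) > 0)
            find_anchor(ctg, genes, min_pct_id) else NULL
        if (!is.null(anchor)) {
            rotated <- rotate_to_anchor(ctg, anchor)
            report$method[i] <- "anchor"
            report$offset[i] <- anchor$contig_start
            report$strand_flipped[i] <- anchor$strand == "-"
            contigs$seq[i] <- rotated$seq
            next
        }
        mid <- fallback_middle_gene(ctg)
        if (is.null(mid)) next # no ORF: left unrotated
        s <- ctg$seq
        off <- mid$offset
        if (mid$strand == "-") {
            s <- revcomp(s)
            off <- nchar(s) - mid$offset - 1L
        }
        contigs$seq[i] <- rotate(s, off %% nchar(s))
        report$method[i] <- "middle_orf"
        report$offset[i] <- mid$offset
        report$strand_flipped[i] <- mid$strand == "-"
    }
    list(contigs = contigs, report = report)
}
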
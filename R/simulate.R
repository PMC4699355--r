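#' Simulation configuration
#'
#' Describes a set of replicons and the pathologies their linear contig
#' representations exhibit, plus the corrected-read model. Supported
#' pathologies (the misassembly modes of linear representations of circular
#' molecules):
#' \describe{
#'   \item{`dup_ends(len)`}{the contig carries a duplicated, optionally
#'     error-mutated ("low-quality") copy of its first `len` bases at its
#'     end.}
#'   \item{`missing(len)`}{`len` bases at the junction are absent.}
#'   \item{`tandem(copies)`}{the whole circle appears `copies` times in one
#'     contig (replicon shorter than the read length).}
#'   \item{`fragmented(n, gap)`}{the circle is split into `n` linear pieces
#'     with `gap` bases lost between consecutive pieces.}
#'   \item{`false_overlap(repeat_len)`}{negative control: a LINEAR truth
#'     flanked by identical `repeat_len` repeats at both ends, so overlap-only
#'     methods see a spurious junction. Reads never cross the ends.}
#'   \item{`none`}{a clean linearization.}
#' }
#'
#' Reads are sampled uniformly around each circle (crossing the origin), on
#' random strands, with normal lengths and optional substitution/indel errors.
#'
#' @param replicons a list; each element a list with `length` (bases),
#'   `pathology` (a list with `type` and the fields above) and optional
#'   `anchor_gene = TRUE` to plant a synthetic anchor gene.
#' @param read_length_mean,read_length_sd read length model in bases
#'   (defaults 10000 and 1000).
#' @param coverage fold coverage of each replicon (default 20).
#' @param per_base_error read error probability (default 0; inputs are
#'   corrected reads).
#' @param dup_error_rate substitution+indel rate inside duplicated
#'   "low-quality" contig ends (default 0.05).
#' @param seed RNG seed; the whole truth set is a deterministic function of
#'   the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(replicons, read_length_mean = 10000,
                       read_length_sd = 1000, coverage = 20,
                       per_base_error = 0, dup_error_rate = 0.05, seed = 1) {
    stopifnot(length(replicons) >= 1, coverage > 0,
              per_base_error >= 0, per_base_error <= 0.2,
              read_length_mean >= 500)
    for (r in replicons) {
        stopifnot(is.numeric(r$length), r$length >= 1000)
        if (r$pathology$type == "tandem") stopifnot(r$pathology$copies >= 2)
    }
    structure(list(replicons = replicons,
                   read_length_mean = read_length_mean,
                   read_length_sd = read_length_sd, coverage = coverage,
                   per_base_error = per_base_error,
                   dup_error_rate = dup_error_rate, seed = seed),
              class = "sim_config")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Substitutions, insertions and deletions at the given per-base rate
# (60/20/20 split), used for "low-quality" duplicated ends and read errors.
mutate_seq <- function(seq, rate) {
    if (rate <= 0 || nchar(seq) == 0) return(seq)
    ch <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    if (!length(hit)) return(seq)
    kind <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                   prob = c(0.6, 0.2, 0.2))
    for (i in seq_along(hit)) {
        p <- hit[i]
        ch[p] <- switch(kind[i],
            sub = sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1),
            ins = paste0(ch[p], sample(c("A", "C", "G", "T"), 1)),
            del = "")
    }
    paste(ch, collapse = "")
}

# A synthetic anchor gene: start codon, stop-free interior, terminal stop.
random_gene <- function(n_codons = 334) {
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste, collapse = "")
    sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
    paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                        collapse = ""), "TAA")
}

#' Generate a ground-truthed fixture
#'
#' Builds random truth replicons, derives one contig per replicon according to
#' its pathology, and samples corrected reads around each circle (or along the
#' linear truth for `false_overlap`). Fully deterministic given the config
#' seed.
#'
#' @param config a [sim_config()].
#' @return A list of class `truth_set`: `truth`, `contigs`, `reads`, `genes`
#'   ([seq_set()]s), a `provenance` table and the `config`.
#' @export
simulate_truth_set <- function(config) {
    set.seed(config$seed)
    truth <- list(); contigs <- list(); reads <- list(); genes <- list()
    prov <- list()
    for (ri in seq_along(config$replicons)) {
        rspec <- config$replicons[[ri]]
        L <- rspec$length
        name <- if (!is.null(rspec$name)) rspec$name else paste0("replicon.", ri)
        pt <- rspec$pathology$type
        circ_truth <- pt != "false_overlap"
        if (circ_truth) {
            tseq <- random_seq(L)
        } else {
            rl <- rspec$pathology$repeat_len
            stopifnot(rl * 2 < L)
            rep_seq <- random_seq(rl)
            tseq <- paste0(rep_seq, random_seq(L - 2 * rl), rep_seq)
        }
        if (isTRUE(rspec$anchor_gene)) {
            g <- random_gene()
            pos <- sample.int(L - nchar(g), 1)
            strand <- sample(c("+", "-"), 1)
            gi <- if (strand == "+") g else revcomp(g)
            tseq <- paste0(substr(tseq, 1, pos), gi,
                           substr(tseq, pos + nchar(g) + 1, L))
            genes[[length(genes) + 1L]] <-
                seq_set(paste0(name, ".anchor"), g)
        }
        truth[[ri]] <- seq_set(name, tseq, circular = circ_truth)

        origin <- if (circ_truth) sample.int(L, 1) - 1L else 0L
        lin <- if (origin > 0) rotate(tseq, origin) else tseq
        ctg <- switch(pt,
            none = seq_set(paste0(name, ".ctg"), lin),
            dup_ends = {
                dup <- substr(lin, 1, rspec$pathology$len)
                seq_set(paste0(name, ".ctg"),
                        paste0(lin, mutate_seq(dup, config$dup_error_rate)))
            },
            missing = seq_set(paste0(name, ".ctg"),
                              substr(lin, 1, L - rspec$pathology$len)),
            tandem = seq_set(paste0(name, ".ctg"),
                             strrep(lin, rspec$pathology$copies)),
            fragmented = {
                n <- rspec$pathology$n; gap <- rspec$pathology$gap
                # breakpoints at roughly equal arcs with jitter, so no piece
                # can be swallowed by its gap
                jit <- sample.int(max(2L, L %/% (4L * n)), n) - 1L
                cuts <- (floor(L * (seq_len(n) - 1) / n) + jit) %% L
                cuts <- sort(cuts)
                pieces <- character(n)
                dd <- paste0(lin, lin)
                for (pi in seq_len(n)) {
                    from <- cuts[pi] + gap
                    to <- if (pi < n) cuts[pi + 1] else cuts[1] + L
                    stopifnot(to - from >= 1000) # config sanity
                    pieces[pi] <- substr(dd, from + 1, to)
                }
                seq_set(paste0(name, ".ctg.", seq_len(n)), pieces)
            },
            false_overlap = seq_set(paste0(name, ".ctg"), lin),
            stop("unknown pathology type: ", pt))
        contigs[[ri]] <- ctg
        prov[[length(prov) + 1L]] <- data.frame(replicon = name, item = ctg$id,
                                 kind = "contig", pathology = pt,
                                 origin = origin, stringsAsFactors = FALSE)

        n_reads <- ceiling(L * config$coverage / config$read_length_mean)
        lens <- pmax(500L, round(rnorm(n_reads, config$read_length_mean,
                                       config$read_length_sd)))
        if (circ_truth) {
            starts <- sample.int(L, n_reads, replace = TRUE) - 1L
            unrolled <- strrep(tseq, ceiling(max(starts + lens) / L))
            rseq <- substring(unrolled, starts + 1, starts + lens)
        } else {
            # The linear truth is a fragment whose assembly broke at the end
            # repeats; its reads come from the surrounding chromosome, whose
            # sequence beyond the fragment differs (other repeat copies have
            # other neighborhoods). Reads therefore run past the fragment
            # ends into foreign flanking sequence instead of stopping dead.
            flank <- config$read_length_mean
            ext <- paste0(random_seq(flank), tseq, random_seq(flank))
            n_reads <- ceiling(nchar(ext) * config$coverage /
                               config$read_length_mean)
            lens <- pmax(500L, round(rnorm(n_reads, config$read_length_mean,
                                           config$read_length_sd)))
            lens <- pmin(lens, nchar(ext))
            starts <- vapply(lens, function(l)
                sample.int(nchar(ext) - l + 1, 1) - 1L, 0L)
            rseq <- substring(ext, starts + 1, starts + lens)
            starts <- starts - flank # provenance in truth coordinates
        }
        flip <- runif(n_reads) < 0.5
        rseq[flip] <- revcomp(rseq[flip])
        if (config$per_base_error > 0)
            rseq <- vapply(rseq, mutate_seq, "", rate = config$per_base_error,
                           USE.NAMES = FALSE)
        rid <- sprintf("%s.read.%04d", name, seq_len(n_reads))
        reads[[ri]] <- seq_set(rid, rseq,
                               qual = strrep("I", nchar(rseq)))
        prov[[length(prov) + 1L]] <- data.frame(
            replicon = name, item = rid, kind = "read", pathology = pt,
            origin = starts, stringsAsFactors = FALSE)
    }
    bindss <- function(l) {
        out <- do.call(rbind, l)
        class(out) <- c("seq_set", "data.frame")
        rownames(out) <- NULL
        out
    }
    structure(list(truth = bindss(truth), contigs = bindss(contigs),
                   reads = bindss(reads),
                   genes = if (length(genes)) bindss(genes) else NULL,
                   provenance = do.call(rbind, prov), config = config),
              class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
    cat("truth_set:", nrow(x$truth), "replicon(s),", nrow(x$contigs),
        "contig(s),", nrow(x$reads), "read(s)\n")
    invisible(x)
}

# Is `out` an exact rotation (either strand) of circular truth `tr`?
rotation_match <- function(out, tr) {
    if (nchar(out) != nchar(tr)) return(FALSE)
    dd <- paste0(tr, tr)
    grepl(out, dd, fixed = TRUE) || grepl(revcomp(out), dd, fixed = TRUE)
}

#' Score pipeline output against simulation truth
#'
#' For every truth replicon the best-matching output contig is found and
#' compared up to rotation and strand (the truth is doubled and searched for
#' the output and its reverse complement). A replicon is correctly
#' circularized when its contig is flagged circular, has zero length
#' difference and matches the truth exactly once around. Output contigs
#' flagged circular whose truth is linear are counted as false
#' circularizations.
#'
#' @param output a [seq_set()] of pipeline output contigs.
#' @param truth_set a [simulate_truth_set()] result.
#' @return A list: per-replicon `report` data frame and scalars
#'   `n_output_contigs` and `false_circularizations`.
#' @export
score_against_truth <- function(output, truth_set) {
    truth <- truth_set$truth
    rows <- list()
    for (ti in seq_len(nrow(truth))) {
        tr <- truth$seq[ti]
        cand <- seq_len(nrow(output))
        best <- NA_integer_; best_exact <- FALSE
        for (oi in cand) {
            if (truth$circular[ti] && rotation_match(output$seq[oi], tr) ||
                !truth$circular[ti] && (output$seq[oi] == tr ||
                                        output$seq[oi] == revcomp(tr))) {
                best <- oi; best_exact <- TRUE
                break
            }
        }
        if (is.na(best) && nrow(output) > 0) {
            # fall back to the contig sharing the most sequence with truth
            ov <- vapply(cand, function(oi) {
                h <- align_all(seq_set("t", tr), output[oi, ],
                               align_params(min_pct_id = 90))
                if (nrow(h) == 0) 0 else
                    as.numeric(interval_union_len(h$ref_start, h$ref_end))
            }, 0)
            if (max(ov) > 0) best <- cand[which.max(ov)]
        }
        matched <- !is.na(best)
        rows[[ti]] <- data.frame(
            replicon = truth$id[ti],
            truth_circular = truth$circular[ti],
            output_contig = if (matched) output$id[best] else NA_character_,
            output_circular = if (matched) output$circular[best] else FALSE,
            length_delta = if (matched) nchar(output$seq[best]) - nchar(tr)
                           else NA_integer_,
            identity = if (best_exact) 100 else NA_real_,
            rotation_invariant_match = best_exact,
            correctly_circularized = matched && best_exact &&
                truth$circular[ti] && output$circular[best],
            falsely_circularized = matched && !truth$circular[ti] &&
                output$circular[best],
            stringsAsFactors = FALSE)
    }
    report <- do.call(rbind, rows)
    list(report = report, n_output_contigs = nrow(output),
         false_circularizations = sum(report$falsely_circularized))
}
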
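#' Pipeline parameters
#'
#' One object holding every stage's tunables, exposed under the names users of
#' the original tooling know. The eight parameters evaluated in the source
#' method's sensitivity analysis are all here: `b2r_length_cutoff` (the
#' long/short contig boundary that controls which reads are reassembled) plus
#' the merge/circularization thresholds. `nanopore = TRUE` applies the
#' relaxed matching preset (`merge_min_id = 85`, `merge_breaklen = 1000`) used
#' for higher-error nanopore assemblies.
#'
#' @param b2r_length_cutoff long/short contig boundary in bases
#'   (default 100000).
#' @param b2r_end_window end-window length for read filtering (default 50000).
#' @param b2r_min_trimmed_len minimum trimmed read length (default 250).
#' @param merge_min_id percent identity for unit-vs-contig matching
#'   (default 95).
#' @param merge_breaklen aligner gap-bridging distance (default 500).
#' @param merge_min_length minimum end-match length for merging (default
#'   4000).
#' @param merge_max_unit_end_dist maximum distance of a match from a unit end
#'   (default 1000).
#' @param merge_max_contig_end_dist maximum distance of a match from a contig
#'   end (default 15000).
#' @param min_contig_cov,min_unit_frac circularization-by-replacement
#'   coverage fractions (defaults 0.95).
#' @param refine_min_contig_len minimum contig length kept (default 2000).
#' @param fixstart_min_id minimum amino-acid identity for anchor genes
#'   (default 80).
#' @param k_ladder assembler overlap ladder (default 127 down to 71).
#' @param nanopore apply the nanopore preset (default FALSE).
#' @return A list of class `pipeline_params` with the per-stage parameter
#'   objects under `$filter`, `$assemble`, `$merge`, `$circularize`,
#'   `$refine`.
#' @export
pipeline_params <- function(b2r_length_cutoff = 100000,
                            b2r_end_window = 50000,
                            b2r_min_trimmed_len = 250,
                            merge_min_id = 95, merge_breaklen = 500,
                            merge_min_length = 4000,
                            merge_max_unit_end_dist = 1000,
                            merge_max_contig_end_dist = 15000,
                            min_contig_cov = 0.95, min_unit_frac = 0.95,
                            refine_min_contig_len = 2000,
                            fixstart_min_id = 80,
                            k_ladder = c(127L, 121L, 111L, 101L, 95L, 91L,
                                         85L, 81L, 75L, 71L),
                            nanopore = FALSE) {
    if (nanopore) {
        merge_min_id <- 85
        merge_breaklen <- 1000
    }
    mp <- merge_params(min_match_len = merge_min_length,
                       max_unit_end_dist = merge_max_unit_end_dist,
                       max_contig_end_dist = merge_max_contig_end_dist,
                       min_pct_id = merge_min_id, breaklen = merge_breaklen)
    structure(list(
        filter = filter_params(length_cutoff = b2r_length_cutoff,
                               end_window = b2r_end_window,
                               min_trimmed_len = b2r_min_trimmed_len),
        assemble = assemble_params(k_ladder = k_ladder),
        merge = mp,
        circularize = circularize_params(min_contig_cov = min_contig_cov,
                                         min_unit_frac = min_unit_frac,
                                         merge_p = mp),
        refine = refine_params(min_contig_len = refine_min_contig_len),
        fixstart_min_id = fixstart_min_id),
        class = "pipeline_params")
}

#' Run the full circularization pipeline
#'
#' Stage order: iterative contig merging to a fixpoint, circularization of
#' each contig (replacement first, then end-joining), refinement (short and
#' contained contigs removed), and start fixing of circular contigs. Absence
#' of circular sequences is a valid result, not an error.
#'
#' @param contigs assembly contigs: a [seq_set()] or FASTA path.
#' @param reads corrected reads: a [seq_set()] or FASTA/FASTQ path.
#' @param params a [pipeline_params()].
#' @param genes anchor genes for start fixing: a [seq_set()], FASTA path, or
#'   `NULL` for the middle-gene fallback only.
#' @param outdir when given, final FASTA, per-stage TSV reports, an
#'   ACT-compatible comparison file and a log are written there.
#' @return A list of class `circweld_result`: final `contigs`, a `summary`
#'   list (contigs in/out, merges, circularizations by path, removals,
#'   rotations), and per-stage detail (`merge_log`, `merge_decisions`,
#'   `circularize_report`, `refine_removed`, `fixstart_report`, `unit_hits`,
#'   `units`).
#' @export
run_pipeline <- function(contigs, reads, params = pipeline_params(),
                         genes = NULL, outdir = NULL) {
    if (is.character(contigs)) contigs <- read_seqs(contigs)
    if (is.character(reads)) reads <- read_seqs(reads)
    if (is.character(genes)) genes <- read_seqs(genes)
    n_in <- nrow(contigs)

    mg <- merge_to_fixpoint(contigs, reads,
                            filter_p = params$filter,
                            assemble_p = params$assemble,
                            merge_p = params$merge)
    circ <- circularize_contigs(mg$contigs, mg$units, params$circularize,
                                hits = mg$hits)
    ref <- refine_contigs(circ$contigs, params$refine)
    fx <- fix_starts(ref$contigs, genes, params$fixstart_min_id)
    final <- fx$contigs
    rownames(final) <- NULL

    summary <- list(
        contigs_in = n_in,
        contigs_out = nrow(final),
        merges_applied = sum(mg$log$merges_applied),
        merge_iterations = mg$n_iterations,
        circularized_replaced = sum(circ$report$action == "replaced"),
        circularized_end_joined = sum(circ$report$action == "end_joined"),
        already_circular = sum(circ$report$action == "already_circular"),
        removed_refine = nrow(ref$removed),
        rotated = sum(fx$report$method %in% c("anchor", "middle_orf")),
        n_circular_out = sum(final$circular))

    res <- structure(list(contigs = final, summary = summary,
                          merge_log = mg$log,
                          merge_decisions = mg$decisions,
                          circularize_report = circ$report,
                          refine_removed = ref$removed,
                          fixstart_report = fx$report,
                          units = mg$units, unit_hits = mg$hits),
                     class = "circweld_result")
    if (!is.null(outdir)) write_pipeline_output(res, outdir)
    res
}

#' @export
print.circweld_result <- function(x, ...) {
    s <- x$summary
    cat("circweld pipeline result\n")
    cat(sprintf("  contigs: %d in -> %d out (%d circular)\n", s$contigs_in,
                s$contigs_out, s$n_circular_out))
    cat(sprintf("  merges applied: %d over %d iteration(s)\n",
                s$merges_applied, s$merge_iterations))
    cat(sprintf("  circularized: %d replaced, %d end-joined, %d already circular\n",
                s$circularized_replaced, s$circularized_end_joined,
                s$already_circular))
    cat(sprintf("  removed in refinement: %d; rotated: %d\n",
                s$removed_refine, s$rotated))
    invisible(x)
}

write_pipeline_output <- function(res, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_seqs(res$contigs, file.path(outdir, "final.fasta"))
    wt <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(res$merge_log, "merge_log.tsv")
    wt(res$merge_decisions, "merge_decisions.tsv")
    wt(res$circularize_report, "circularize_report.tsv")
    wt(res$refine_removed, "refine_removed.tsv")
    wt(res$fixstart_report, "fixstart_report.tsv")
    if (nrow(res$units) > 0)
        write_seqs(res$units, file.path(outdir, "local_units.fasta"))
    write_act_comparison(res$unit_hits, file.path(outdir, "act_comparison.crunch"))
    sm <- res$summary
    writeLines(paste(names(sm), unlist(sm), sep = "\t"),
               file.path(outdir, "summary.tsv"))
    invisible(outdir)
}

#' Write an ACT-compatible comparison file
#'
#' Exports hits in crunch-style tab format (score, percent identity,
#' query start, query end, query id, reference start, reference end,
#' reference id), 1-based inclusive coordinates, reverse hits encoded by
#' descending query coordinates - the file format the Artemis Comparison Tool
#' loads for comparing the input assembly against the reassembled units.
#'
#' @param hits a hit data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_act_comparison <- function(hits, path) {
    if (nrow(hits) == 0) {
        file.create(path)
        return(invisible(path))
    }
    score <- round(hits$aln_len * hits$pct_id / 100)
    qs <- ifelse(hits$strand == "+", hits$qry_start + 1L, hits$qry_end)
    qe <- ifelse(hits$strand == "+", hits$qry_end, hits$qry_start + 1L)
    tab <- data.frame(score, pct_id = round_half_up(hits$pct_id, 2),
                      qs, qe, qry_id = hits$qry_id,
                      rs = hits$ref_start + 1L, re = hits$ref_end,
                      ref_id = hits$ref_id)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
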
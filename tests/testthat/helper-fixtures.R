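# Shared fixture builders. Everything is generated in code; tests set their
# own seeds so files are deterministic and independent.

rnd_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# Error-free reads tiling a circle (or a linear sequence), forward strand,
# evenly spaced starts: the minimal well-behaved input for the assembler.
tiling_reads <- function(seq, read_len, step, circular = TRUE,
                         prefix = "read") {
    L <- nchar(seq)
    if (circular) {
        starts <- seq(0, L - 1, by = step)
        dd <- strrep(seq, ceiling((max(starts) + read_len) / L))
        out <- substring(dd, starts + 1, starts + read_len)
    } else {
        starts <- seq(0, L - read_len, by = step)
        if (max(starts) < L - read_len) starts <- c(starts, L - read_len)
        out <- substring(seq, starts + 1, starts + read_len)
    }
    seq_set(sprintf("%s.%03d", prefix, seq_along(out)), out)
}

# One-replicon simulation shorthand.
sim1 <- function(type, L, seed, ..., anchor_gene = FALSE, read_length = 10000,
                 coverage = 20) {
    simulate_truth_set(sim_config(
        list(list(length = L, pathology = c(list(type = type), list(...)),
                  anchor_gene = anchor_gene)),
        read_length_mean = read_length, read_length_sd = read_length / 10,
        coverage = coverage, seed = seed))
}

# Pipeline parameters for plasmid-scale fixtures: every contig in the
# short-contig regime (all reads used for local assembly).
plasmid_params <- function(...) pipeline_params(b2r_length_cutoff = 3e5, ...)

# Synonymously recode a fraction of codons of an ORF (protein unchanged).
synonymize <- function(gene, frac, seed = 1) {
    all_cod <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 c("A", "C", "G", "T")), 1, paste,
                     collapse = "")
    # no.init.codon: otherwise TTG/CTG "translate" to M as initiators
    aas <- vapply(all_cod, function(cd) as.character(
        Biostrings::translate(Biostrings::DNAString(cd),
                              no.init.codon = TRUE)), "")
    n <- nchar(gene) %/% 3
    codons <- substring(gene, 3 * (0:(n - 1)) + 1, 3 * (1:n))
    idx <- sample(n, round(frac * n))
    for (i in idx) {
        alt <- setdiff(all_cod[aas == aas[[match(codons[i], all_cod)]]],
                       codons[i])
        if (length(alt)) codons[i] <- alt[1]
    }
    paste(codons, collapse = "")
}
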
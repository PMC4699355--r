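#' @useDynLib circweld, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head read.table tail write.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Create a set of sequence records
#'
#' A `seq_set` is the container used throughout the package: a data frame with
#' one row per record and columns `id`, `seq`, `qual` (NA when absent) and
#' `circular`. Sequences are uppercase strings over A, C, G, T, N; ids are
#' unique and contain no whitespace.
#'
#' @param id character vector of record ids.
#' @param seq character vector of nucleotide sequences (case-insensitive).
#' @param qual optional per-base quality strings (Phred+33), same lengths as
#'   `seq`.
#' @param circular logical flag(s), recycled; marks records known to represent
#'   a full circular molecule stored exactly once around.
#' @return A `seq_set` data frame.
#' @export
seq_set <- function(id, seq, qual = NA_character_, circular = FALSE) {
    id <- as.character(id)
    seq <- toupper(as.character(seq))
    if (length(id) != length(seq)) stop("id and seq lengths differ")
    if (any(is.na(id)) || any(id == "") || any(grepl("\\s", id)))
        stop("ids must be non-empty and contain no whitespace")
    if (anyDuplicated(id))
        stop("duplicate record id(s): ", paste(unique(id[duplicated(id)]), collapse = ", "))
    if (any(nchar(seq) < 1)) stop("zero-length sequence for id: ",
                                  paste(id[nchar(seq) < 1], collapse = ", "))
    bad <- grepl("[^ACGTN]", seq)
    if (any(bad))
        stop("invalid characters (outside ACGTN) in record(s): ",
             paste(id[bad], collapse = ", "))
    qual <- rep_len(as.character(qual), length(seq))
    mism <- !is.na(qual) & nchar(qual) != nchar(seq)
    if (any(mism))
        stop("quality length != sequence length for record(s): ",
             paste(id[mism], collapse = ", "))
    out <- data.frame(id = id, seq = seq, qual = qual,
                      circular = rep_len(as.logical(circular), length(seq)),
                      stringsAsFactors = FALSE)
    class(out) <- c("seq_set", "data.frame")
    out
}

seq_lengths <- function(x) setNames(nchar(x$seq), x$id)

get_seq <- function(x, id) {
    i <- match(id, x$id)
    if (is.na(i)) stop("no record with id: ", id)
    x$seq[i]
}

#' Read sequences from FASTA or FASTQ
#'
#' FASTA parsing is delegated to Biostrings; FASTQ records are read as
#' four-line Sanger/Phred+33 records so that malformed files are reported with
#' a line number. Sequences are uppercased; characters outside A, C, G, T, N
#' and duplicate ids are rejected. A ` circular=true` token in a FASTA/FASTQ
#' description sets the record's circular flag (the dialect this package
#' writes).
#'
#' @param path file to read.
#' @param format `"fasta"`, `"fastq"` or `"auto"` (sniff the first character).
#' @return A [seq_set()].
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        first <- substr(readLines(path, n = 1L), 1, 1)
        if (length(first) == 0) stop("empty file: ", path)
        format <- if (first == ">") "fasta" else if (first == "@") "fastq" else
            stop("cannot determine format of ", path, " (first character '", first, "')")
    }
    if (format == "fasta") {
        recs <- tryCatch(Biostrings::readBStringSet(path),
                         error = function(e) stop("parse error in ", path, ": ",
                                                  conditionMessage(e), call. = FALSE))
        if (length(recs) == 0) stop("no records in ", path)
        desc <- names(recs)
        ids <- sub("\\s.*$", "", desc)
        circ <- grepl("(^|\\s)circular=true(\\s|$)", desc)
        seq_set(ids, as.character(recs), circular = circ)
    } else {
        lines <- readLines(path)
        if (length(lines) %% 4 != 0)
            stop("parse error in ", path, ": line count ", length(lines),
                 " is not a multiple of 4")
        n <- length(lines) %/% 4
        hdr <- lines[seq(1, by = 4, length.out = n)]
        seqs <- lines[seq(2, by = 4, length.out = n)]
        plus <- lines[seq(3, by = 4, length.out = n)]
        quals <- lines[seq(4, by = 4, length.out = n)]
        bad <- which(substr(hdr, 1, 1) != "@")
        if (length(bad))
            stop("parse error in ", path, ": line ", (bad[1] - 1) * 4 + 1,
                 ": expected '@' header")
        bad <- which(substr(plus, 1, 1) != "+")
        if (length(bad))
            stop("parse error in ", path, ": line ", (bad[1] - 1) * 4 + 3,
                 ": expected '+' separator")
        bad <- which(nchar(quals) != nchar(seqs))
        if (length(bad))
            stop("parse error in ", path, ": line ", (bad[1] - 1) * 4 + 4,
                 ": quality length differs from sequence length")
        desc <- sub("^@", "", hdr)
        ids <- sub("\\s.*$", "", desc)
        circ <- grepl("(^|\\s)circular=true(\\s|$)", desc)
        seq_set(ids, seqs, qual = quals, circular = circ)
    }
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTA is wrapped at 60 columns. Records flagged circular gain a
#' ` circular=true` description token. FASTQ requires qualities on every
#' record (qualities are carried through, never interpreted).
#'
#' @param x a [seq_set()].
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_seqs <- function(x, path, format = c("fasta", "fastq")) {
    format <- match.arg(format)
    desc <- ifelse(x$circular, paste0(x$id, " circular=true"), x$id)
    if (format == "fasta") {
        recs <- Biostrings::BStringSet(x$seq)
        names(recs) <- desc
        Biostrings::writeXStringSet(recs, path, width = 60L)
    } else {
        if (any(is.na(x$qual)))
            stop("cannot write FASTQ: missing qualities for record(s): ",
                 paste(x$id[is.na(x$qual)], collapse = ", "))
        out <- character(4 * nrow(x))
        out[seq(1, by = 4, length.out = nrow(x))] <- paste0("@", desc)
        out[seq(2, by = 4, length.out = nrow(x))] <- x$seq
        out[seq(3, by = 4, length.out = nrow(x))] <- "+"
        out[seq(4, by = 4, length.out = nrow(x))] <- x$qual
        writeLines(out, path)
    }
    invisible(path)
}

#' Reverse complement
#'
#' @param seq nucleotide string(s) over A, C, G, T, N; N maps to N.
#' @return reverse complement string(s).
#' @export
revcomp <- function(seq) {
    if (any(grepl("[^ACGTN]", seq <- toupper(seq))))
        stop("invalid characters in sequence (alphabet is ACGTN)")
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Rotate a sequence to a new start position
#'
#' Returns `seq[new_start..] + seq[..new_start]` using 0-based offsets; the
#' operation circular contigs undergo when their start is moved to an anchor
#' gene.
#'
#' @param seq a single sequence string.
#' @param new_start 0-based offset of the base that becomes position 0.
#' @return rotated string, same length.
#' @export
rotate <- function(seq, new_start) {
    n <- nchar(seq)
    if (length(seq) != 1) stop("rotate() takes a single sequence")
    if (!is.numeric(new_start) || length(new_start) != 1 ||
        new_start != floor(new_start) || new_start < 0 || new_start >= n)
        stop("new_start must be an integer in [0, ", n - 1, "]")
    if (new_start == 0) return(seq)
    paste0(substr(seq, new_start + 1, n), substr(seq, 1, new_start))
}

# Integer codes for C++ kernels: A,C,G,T -> 0..3, N -> -1.
.dna_code_table <- local({
    tab <- rep(-1L, 256)
    tab[utf8ToInt("A") + 1] <- 0L
    tab[utf8ToInt("C") + 1] <- 1L
    tab[utf8ToInt("G") + 1] <- 2L
    tab[utf8ToInt("T") + 1] <- 3L
    tab
})

dna_codes <- function(seq) .dna_code_table[utf8ToInt(seq) + 1]

# Amino-acid codes for the translated search: 20 residues plus '*' (stop,
# must match a stop) are >= 0; anything else (X, ambiguous) is -1.
.aa_code_table <- local({
    tab <- rep(-1L, 256)
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY*", "")[[1]]
    for (i in seq_along(aas)) tab[utf8ToInt(aas[i]) + 1] <- i - 1L
    tab
})

aa_codes <- function(seq) .aa_code_table[utf8ToInt(seq) + 1]
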
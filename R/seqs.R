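## Protein/CDS sequence utilities: translation, pairwise identity,
## KEN-box scanning, FASTA IO.

#' Translate a coding sequence
#'
#' Standard genetic code, translated up to (and excluding) the first stop
#' codon. In strict mode a stop before the final codon position is an error
#' (truncated or frame-shifted CDS); otherwise translation silently stops
#' there.
#'
#' @param seq nucleotide sequence: single character string (ACGT/U, case
#'   insensitive) or a `Biostrings::DNAString`. Length must be divisible
#'   by 3.
#' @param strict error on internal stop codons (default `TRUE`).
#' @return Protein sequence as a character string.
#' @export
#' @examples
#' translate_cds("ATGAAATAA")   # "MK"
translate_cds <- function(seq, strict = TRUE) {
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("'seq' must be a single non-empty nucleotide string")
  seq <- toupper(gsub("U", "T", toupper(seq)))
  if (grepl("[^ACGT]", seq))
    stop("invalid nucleotide characters in CDS")
  if (nchar(seq) %% 3L != 0L)
    stop("CDS length (", nchar(seq), ") is not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq)))
  stop_pos <- regexpr("*", aa, fixed = TRUE)
  if (stop_pos == -1L) return(aa)
  if (strict && stop_pos < nchar(aa))
    stop("internal stop codon at amino-acid position ", stop_pos)
  substr(aa, 1L, stop_pos - 1L)
}

#' Percent identity between two protein sequences
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 scoring and affine
#' gaps (open 10, extend 0.5); identity is the fraction of identical
#' residues over alignment columns, excluding columns gapped in both
#' sequences, times 100.
#'
#' @param a,b protein sequences (character strings or `AAString`).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' pairwise_identity("MKTAYIAKQR", "MKTAYIAKQW")   # 90
pairwise_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cols <- !(sa == "-" & sb == "-")
  100 * sum(sa[cols] == sb[cols]) / sum(cols)
}

#' Scan a protein for KEN-box motifs
#'
#' Reports all occurrences of the K-E-N degradation motif (recognised by
#' the anaphase-promoting complex) as 1-based spans. The default pattern is
#' the minimal tripeptide `"KEN"`; any regular expression over the amino
#' acid alphabet may be supplied for extended consensus variants.
#'
#' @param seq protein sequence (character string or `AAString`).
#' @param pattern regular expression to scan for (default `"KEN"`).
#' @return Data frame with columns `start` and `end` (0 rows when absent).
#' @export
#' @examples
#' scan_ken_box("AAKENAA")
scan_ken_box <- function(seq, pattern = "KEN") {
  seq <- toupper(as.character(seq))
  m <- gregexpr(pattern, seq)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Read or write FASTA sequences
#'
#' Thin wrappers around Biostrings FASTA IO returning plain named character
#' vectors. Duplicate record identifiers are an error on read; output is
#' wrapped at 60 columns.
#'
#' @param path file path.
#' @param alphabet `"AA"` (default) or `"DNA"`.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  set <- if (alphabet == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  stats::setNames(as.character(set), ids)
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}
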
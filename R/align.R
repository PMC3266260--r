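# Internal pairwise-alignment helpers. All protein alignments use BLOSUM62
# with gap open 10 / extension 0.5 (EMBOSS needle-style defaults);
# nucleotide local alignments use +5/-4 with the same gap costs.

.align_cache <- new.env()

blosum62 <- function() {
  if (is.null(.align_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_cache$BLOSUM62 <- e$BLOSUM62
  }
  .align_cache$BLOSUM62
}

# fast plain-string reverse complement and translation (standard code,
# no initiator-codon special-casing; codons with N translate to X)
revcomp_str <- function(s) {
  x <- rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]])
  paste(x, collapse = "")
}

.gc_env <- new.env()
translate_str <- function(s) {
  n <- nchar(s) %/% 3 * 3
  if (n < 3) return("")
  if (is.null(.gc_env$code)) .gc_env$code <- Biostrings::GENETIC_CODE
  starts <- seq.int(1, n, by = 3)
  codons <- substring(s, starts, starts + 2)
  aa <- .gc_env$code[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Global protein alignment; returns aligned rows as character vectors of
# single residues ("-" for gaps) plus the raw score.
align_global_aa <- function(a, b, config = NULL) {
  config <- default_config(config)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(),
    gapOpening = config$aa_gap_open, gapExtension = config$aa_gap_ext,
    type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(a = pat, b = sub, score = Biostrings::score(aln))
}

align_local_aa <- function(a, b, config = NULL) {
  config <- default_config(config)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(),
    gapOpening = config$aa_gap_open, gapExtension = config$aa_gap_ext,
    type = "local")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(a = pat, b = sub, score = Biostrings::score(aln),
       a_start = BiocGenerics::start(Biostrings::pattern(aln)),
       a_end = BiocGenerics::end(Biostrings::pattern(aln)),
       b_start = BiocGenerics::start(Biostrings::subject(aln)),
       b_end = BiocGenerics::end(Biostrings::subject(aln)))
}

align_local_nt <- function(a, b, config = NULL) {
  config <- default_config(config)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$nt_match, mismatch = config$nt_mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat,
    gapOpening = config$nt_gap_open, gapExtension = config$nt_gap_ext,
    type = "local")
  list(score = Biostrings::score(aln),
       a_start = BiocGenerics::start(Biostrings::pattern(aln)),
       a_end = BiocGenerics::end(Biostrings::pattern(aln)),
       b_start = BiocGenerics::start(Biostrings::subject(aln)),
       b_end = BiocGenerics::end(Biostrings::subject(aln)),
       a_aln = as.character(Biostrings::alignedPattern(aln)),
       b_aln = as.character(Biostrings::alignedSubject(aln)))
}

# Residue index of each alignment row at every column (NA at gaps).
alignment_index_map <- function(chars) {
  idx <- cumsum(chars != "-")
  idx[chars == "-"] <- NA_integer_
  idx
}

# Percent identity over aligned (gap-free) columns.
alignment_identity_pct <- function(a_chars, b_chars) {
  both <- a_chars != "-" & b_chars != "-"
  if (!any(both)) return(0)
  100 * sum(a_chars[both] == b_chars[both] & a_chars[both] != "X") / sum(both)
}

# Percent of columns (gaps included in the denominator) whose residue pair
# has a positive BLOSUM62 score -- the "similarity" used for AIP
# conservation calls.
alignment_similarity_pct <- function(a_chars, b_chars) {
  n <- length(a_chars)
  if (n == 0) return(0)
  both <- a_chars != "-" & b_chars != "-"
  if (!any(both)) return(0)
  m <- blosum62()
  keep <- both & a_chars %in% rownames(m) & b_chars %in% colnames(m)
  pos <- sum(m[cbind(a_chars[keep], b_chars[keep])] > 0)
  100 * pos / n
}

# Alignment column holding residue `pos` of the given row; 0 when pos == 0.
column_of_residue <- function(chars, pos) {
  if (pos == 0) return(0L)
  w <- which(cumsum(chars != "-") == pos & chars != "-")
  if (length(w) == 0) NA_integer_ else w[1]
}
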
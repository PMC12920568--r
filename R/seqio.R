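# Sequence I/O: FASTA and GFF3 plumbing plus translation of called ORFs.
# All coordinates inside the package are 0-based half-open on the forward
# strand; GFF3/BED conversion happens only at the file boundary.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Read a FASTA file into a tibble
#'
#' One row per record. Sequences are uppercased; IUPAC ambiguity letters other
#' than the four bases are collapsed to `N` (DNA) or to `X` (protein), so
#' downstream code only ever sees the canonical alphabets.
#'
#' @param path Path to a FASTA file (DNA or protein).
#' @param type `"dna"` or `"protein"`; controls the ambiguity mapping.
#' @return A tibble with columns `id`, `description`, `sequence`, `length`.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate record IDs: ", paste(dups, collapse = ", "))
  }
  seqs <- unname(toupper(as.character(set)))
  seqs <- normalize_alphabet(seqs, type)
  tibble::tibble(
    id = unname(ids),
    description = unname(desc),
    sequence = unname(seqs),
    length = nchar(seqs)
  )
}

# Collapse any out-of-alphabet letter to the wildcard of the given alphabet.
normalize_alphabet <- function(seqs, type) {
  if (type == "dna") {
    gsub("[^ACGT]", "N", seqs)
  } else {
    gsub(paste0("[^", paste(AA_ALPHABET[AA_ALPHABET != "X"], collapse = ""), "]"),
         "X", seqs)
  }
}

#' Write a tibble of sequence records as wrapped FASTA
#'
#' @param records Tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(nrow(records) > 0L)
  set <- Biostrings::BStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else
    rep("", nrow(records))
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Write gene calls as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive convention of GFF3; the score column carries the model
#' probability and the feature type is `CDS`.
#'
#' @param calls Tibble with columns `seq_id`, `start`, `end`, `strand` and
#'   optionally `probability` (otherwise score is `NA`).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff <- function(calls, path, source = "orf2pep") {
  if (nrow(calls) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  stopifnot(all(calls$start < calls$end))
  gr <- GenomicRanges::GRanges(
    seqnames = calls$seq_id,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
    strand = calls$strand
  )
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$score <-
    if ("probability" %in% names(calls)) calls$probability else NA_real_
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <-
    if ("orf_id" %in% names(calls)) calls$orf_id else
      paste0("call", seq_len(nrow(calls)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read GFF3/BED annotations into a tibble of 0-based half-open intervals
#'
#' @param path GFF3 or BED file; format is inferred from the extension.
#' @return Tibble with columns `seq_id`, `start`, `end`, `strand`, and `score`
#'   where present.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path)
  tibble::tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    score = if (!is.null(S4Vectors::mcols(gr)$score)) {
      as.numeric(S4Vectors::mcols(gr)$score)
    } else NA_real_
  )
}

#' Write ORF candidates as BED6
#'
#' BED is natively 0-based half-open, so coordinates pass through unchanged.
#' The score column is left blank (`0`) at the candidate stage.
#'
#' @param candidates Tibble with `seq_id`, `start`, `end`, `strand` and
#'   optionally `orf_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(candidates, path) {
  name <- if ("orf_id" %in% names(candidates)) candidates$orf_id else
    paste0("orf", seq_len(nrow(candidates)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   candidates$seq_id, candidates$start, candidates$end,
                   name, 0L, candidates$strand)
  writeLines(lines, path)
  invisible(path)
}

# NCBI translation table 11 (bacterial/archaeal/plant-plastid), the code for
# the prokaryotic scope of this package.
genetic_code_11 <- function() Biostrings::getGeneticCode("11")

#' Translate an ORF nucleotide sequence to a peptide
#'
#' Uses NCBI translation table 11. A codon containing `N` renders `X`. When
#' `is_start_codon_orf` is `TRUE` the first codon renders `M` regardless of
#' identity (alternative starts ATG/CTG/GTG/TTG all initiate with
#' formyl-methionine in bacteria). A trailing stop codon is dropped from the
#' peptide; an internal stop is an error.
#'
#' @param nt_seq DNA string; an incomplete trailing codon is trimmed.
#' @param is_start_codon_orf Does the ORF begin at a start codon (complete or
#'   3'-truncated candidates)? Default `TRUE`.
#' @return The peptide as a character scalar.
#' @export
translate_orf <- function(nt_seq, is_start_codon_orf = TRUE) {
  code <- genetic_code_11()
  n <- nchar(nt_seq) %/% 3L
  if (n == 0L) stop("sequence shorter than one codon")
  codons <- substring(nt_seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N (or other wildcards)
  if (is_start_codon_orf) aa[1L] <- "M"
  stops <- which(aa == "*")
  if (length(stops) > 0L) {
    if (stops[1L] < n || length(stops) > 1L) {
      off <- (stops[stops < n | duplicated(stops)][1L] - 1L) * 3L
      stop("internal stop codon at nucleotide offset ", off)
    }
    aa <- aa[-n]
  }
  paste(aa, collapse = "")
}

#' Translate retained gene calls into a peptide tibble
#'
#' @param calls Tibble of gene calls carrying `nt_seq` (coding-strand
#'   sequence) and `orf_id`; completeness (if present) decides whether the
#'   first codon is forced to `M`.
#' @return Tibble with `id`, `sequence`, `length`, suitable for
#'   [write_fasta()] and the peptide classifier.
#' @export
translate_calls <- function(calls) {
  stopifnot(all(c("orf_id", "nt_seq") %in% names(calls)))
  has_start <- if ("completeness" %in% names(calls)) {
    calls$completeness %in% c("complete", "missing3")
  } else rep(TRUE, nrow(calls))
  pep <- purrr::map2_chr(calls$nt_seq, has_start, translate_orf)
  tibble::tibble(id = calls$orf_id, sequence = pep, length = nchar(pep))
}
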
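#' Write parental references as FASTA
#'
#' @param refs A `parental_refs` object.
#' @param path_a,path_b Output FASTA paths for genomes A and B.
#' @return Invisibly, the two paths.
#' @export
write_ref_fasta <- function(refs, path_a, path_b) {
  a <- Biostrings::DNAStringSet(refs$seq_A)
  b <- Biostrings::DNAStringSet(refs$seq_B)
  Biostrings::writeXStringSet(a, path_a)
  Biostrings::writeXStringSet(b, path_b)
  invisible(c(path_a, path_b))
}

#' Read a FASTA file into (id, sequence) pairs
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Load a reference pair from two FASTA files
#'
#' The two files must contain the same gene identifiers (1:1 orthology) and
#' equal-length orthologs.
#'
#' @param path_a,path_b FASTA paths.
#' @return A `parental_refs` object.
#' @export
read_ref_fasta <- function(path_a, path_b) {
  a <- read_fasta(path_a)
  b <- read_fasta(path_b)
  if (!setequal(names(a), names(b)))
    stop("reference FASTA files do not share a 1:1 gene set")
  b <- b[names(a)]
  if (any(nchar(a) != nchar(b)))
    stop("orthologs differ in length; substitution-only divergence expected")
  structure(list(gene_id = names(a), seq_A = a, seq_B = b,
                 divergence_rate = NA_real_, seed = NA_integer_),
            class = "parental_refs")
}

#' Write reads as FASTQ (Phred+33)
#'
#' Qualities are constant `"I"` (Q40); downstream classification never
#' consults them.
#'
#' @param reads Data frame with `read_id` and `seq`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$seq),
                 function(n) paste(rep("I", n), collapse = ""), "")
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file (strict four-line records)
#'
#' @param path FASTQ path.
#' @return Data frame `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (", path, "): ", length(lines),
         " lines is not a multiple of 4")
  idx <- seq(1L, length(lines), by = 4L)
  head_ok <- startsWith(lines[idx], "@")
  if (!all(head_ok))
    stop("malformed FASTQ (", path, "): header expected at line ",
         idx[which(!head_ok)[1]])
  plus_ok <- startsWith(lines[idx + 2L], "+")
  if (!all(plus_ok))
    stop("malformed FASTQ (", path, "): '+' separator expected at line ",
         idx[which(!plus_ok)[1]] + 2L)
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  len_ok <- nchar(seqs) == nchar(quals)
  if (!all(len_ok))
    stop("malformed FASTQ (", path,
         "): sequence/quality length mismatch at line ",
         idx[which(!len_ok)[1]] + 1L)
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
             seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write accepted pair alignments as minimal SAM
#'
#' Emits `@HD`/`@SQ` headers for one genome and one line per mate of every
#' species-specific (or parental accepted) pair assigned to that genome.
#' Internal 0-based positions are converted to 1-based SAM `POS`; the `NM`
#' tag carries the per-mate mismatch count. Flags encode paired,
#' proper-pair, mate strands and first/second-in-pair.
#'
#' @param calls An `origin_calls` data frame.
#' @param refs A `parental_refs` object (for `@SQ` lengths).
#' @param genome `"A"` or `"B"`: which genome's assignments to write.
#' @param path Output path.
#' @param read_length Mate length used to locate the reverse mate.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(calls, refs, genome = c("A", "B"), path,
                      read_length = 100L) {
  genome <- match.arg(genome)
  lens <- nchar(if (genome == "A") refs$seq_A else refs$seq_B)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", refs$gene_id, lens))
  want <- paste0(genome, "_specific")
  sub <- calls[calls$call == want & !is.na(calls$gene_id), , drop = FALSE]
  body <- character(0)
  if (nrow(sub)) {
    m1_fwd <- sub$strand1 == "+"
    pos1 <- ifelse(m1_fwd, sub$fwd_pos, sub$rev_pos) + 1L
    pos2 <- ifelse(m1_fwd, sub$rev_pos, sub$fwd_pos) + 1L
    flag1 <- 1L + 2L + 64L + ifelse(m1_fwd, 32L, 16L)
    flag2 <- 1L + 2L + 128L + ifelse(m1_fwd, 16L, 32L)
    tlen <- abs(sub$rev_pos + read_length - sub$fwd_pos)
    l1 <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t%d\t*\t*\tNM:i:%d",
                  sub$read_pair_id, flag1, sub$gene_id, pos1, read_length,
                  pos2, ifelse(m1_fwd, tlen, -tlen), sub$mm1)
    l2 <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t%d\t*\t*\tNM:i:%d",
                  sub$read_pair_id, flag2, sub$gene_id, pos2, read_length,
                  pos1, ifelse(m1_fwd, -tlen, tlen), sub$mm2)
    body <- as.vector(rbind(l1, l2))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a tab-separated table
#'
#' @param x Data frame or matrix.
#' @param path Output path.
#' @param rownames_as Optional column name under which to emit row names
#'   (used for count matrices with genes as rows).
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(stats::setNames(list(rownames(x)), rownames_as),
                    as.data.frame(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
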
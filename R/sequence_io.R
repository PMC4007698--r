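#' Read a genome or CDS FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that validates the
#' file, upper-cases all bases and checks the alphabet against the IUPAC
#' nucleotide codes. Record order is preserved; the full FASTA header is
#' kept as the element name.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per FASTA record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(x) == 0L) {
    stop("malformed FASTA in '", path, "': no records found", call. = FALSE)
  }
  if (any(Biostrings::width(x) == 0L)) {
    bad <- names(x)[Biostrings::width(x) == 0L][1L]
    stop("malformed FASTA in '", path, "': empty record '", bad, "'",
         call. = FALSE)
  }
  # DNAStringSet enforces the IUPAC alphabet and upper-cases on read
  x
}

#' Write sequences to FASTA
#'
#' @param x A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

# split a FASTA header into id (first token) and description (rest)
split_header <- function(header) {
  id <- sub("\\s.*$", "", header)
  desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  list(id = id, description = desc)
}

#' GC percentage of sequences
#'
#' GC% is computed as 100 (G + C) / (A + C + G + T): ambiguity codes
#' (N and the other IUPAC letters) are excluded from both numerator and
#' denominator, so assembly gaps do not bias the estimate.
#'
#' @param x A [Biostrings::DNAStringSet], [Biostrings::DNAString] or
#'   character vector of sequences.
#' @return Numeric vector of GC percentages; `NA` where a sequence has no
#'   unambiguous base.
#' @export
gc_percent <- function(x) {
  counts <- base_counts(x)
  denom <- rowSums(counts)
  ifelse(denom > 0, 100 * (counts[, "G"] + counts[, "C"]) / denom, NA_real_)
}

# A/C/G/T counts as a matrix, one row per sequence
base_counts <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (inherits(x, "DNAString")) x <- Biostrings::DNAStringSet(list(x))
  Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"), OR = 0)
}

#' Assembly scaffold statistics around a length cutoff
#'
#' Computes the genome-wide GC level and the partition of an assembly's
#' DNA into records shorter than, versus at least as long as, a length
#' cutoff, in megabases and as percentages of the total. The cutoff is
#' inclusive on the large side: a record of exactly `cutoff` bases counts
#' in the at-or-above class.
#'
#' @param assembly A [Biostrings::DNAStringSet] (e.g. from [read_fasta()]).
#' @param cutoff Length cutoff in bases (default 100 kb).
#' @return An object of class `assembly_stats`: a list with `gc_percent`,
#'   `n_records`, `total_mb`, `mb_below_cutoff`, `mb_at_or_above_cutoff`,
#'   `pct_below`, `pct_at_or_above` and `cutoff`.
#' @export
scaffold_stats <- function(assembly, cutoff = 100000L) {
  if (length(assembly) == 0L) {
    stop("empty assembly", call. = FALSE)
  }
  counts <- base_counts(assembly)
  tot <- sum(counts)
  gc <- if (tot > 0) 100 * sum(counts[, c("G", "C")]) / tot else NA_real_
  len <- Biostrings::width(assembly)
  below <- sum(as.numeric(len[len < cutoff]))
  above <- sum(as.numeric(len[len >= cutoff]))
  total <- below + above
  structure(list(
    gc_percent = gc,
    n_records = length(assembly),
    total_mb = total / 1e6,
    mb_below_cutoff = below / 1e6,
    mb_at_or_above_cutoff = above / 1e6,
    pct_below = 100 * below / total,
    pct_at_or_above = 100 * above / total,
    cutoff = cutoff
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "Assembly: %d records, %.1f Mb, GC %.1f%%\n", x$n_records, x$total_mb,
    x$gc_percent))
  cat(sprintf("  < %g bases: %.1f Mb (%.1f%%)\n", x$cutoff,
              x$mb_below_cutoff, x$pct_below))
  cat(sprintf("  >= %g bases: %.1f Mb (%.1f%%)\n", x$cutoff,
              x$mb_at_or_above_cutoff, x$pct_at_or_above))
  invisible(x)
}

#' Default CDS description-exclusion keywords
#'
#' The header keywords used to discard genes that are not reliable,
#' experimentally supported protein-coding sequences: partial entries,
#' putative and predicted annotations, hypothetical proteins, structural
#' RNAs and mitochondrial genes.
#'
#' @return Character vector of keywords matched case-insensitively as
#'   substrings of the FASTA description.
#' @export
default_exclusion_keywords <- function() {
  c("partial", "putative", "synthetic construct", "predicted",
    "not experimental", "hypothetical protein", "r-RNA", "t-RNA",
    "ribosomal", "mitochondrial")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Clean a CDS set
#'
#' Applies, in order: (1) case-insensitive substring matching of exclusion
#' keywords against each record's description; (2) structural checks on the
#' survivors -- length divisible by 3, leading start codon, terminal stop
#' codon, no internal stop codon; (3) removal of exact duplicate sequences,
#' keeping the first occurrence. Every input record lands in exactly one of
#' the two output sets; rejected records carry a `rejection_reason`.
#'
#' @param cds A named [Biostrings::DNAStringSet] of coding sequences
#'   (names are FASTA headers) or a named character vector.
#' @param exclusion_keywords Keywords matched against descriptions;
#'   defaults to [default_exclusion_keywords()].
#' @param start_codons Accepted initiator codons (default `"ATG"` only).
#' @param stop_codons Accepted stop codons (default TAA/TAG/TGA, the
#'   standard nuclear code; pass ciliate-style reassignments here if
#'   needed).
#' @return A list with data frames `accepted` and `rejected`; both have
#'   columns `id`, `description`, `sequence`, and `rejected` additionally
#'   has `rejection_reason` (one of `keyword-excluded`, `no-start`,
#'   `no-stop`, `internal-stop`, `length-not-multiple-of-3`, `redundant`).
#' @export
clean_cds <- function(cds,
                      exclusion_keywords = default_exclusion_keywords(),
                      start_codons = "ATG",
                      stop_codons = STOP_CODONS) {
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  headers <- names(cds)
  if (is.null(headers)) headers <- as.character(seq_along(cds))
  hd <- split_header(headers)
  seqs <- as.character(cds)
  n <- length(seqs)
  reason <- rep(NA_character_, n)

  if (length(exclusion_keywords)) {
    desc_l <- tolower(hd$description)
    hit <- Reduce(`|`, lapply(tolower(exclusion_keywords), function(k) {
      grepl(k, desc_l, fixed = TRUE)
    }))
    reason[hit] <- "keyword-excluded"
  }

  todo <- which(is.na(reason))
  for (i in todo) {
    s <- seqs[i]
    len <- nchar(s)
    if (len %% 3L != 0L) { reason[i] <- "length-not-multiple-of-3"; next }
    codons <- substring(s, seq(1L, len, 3L), seq(3L, len, 3L))
    if (!(codons[1L] %in% start_codons)) { reason[i] <- "no-start"; next }
    last <- codons[length(codons)]
    if (!(last %in% stop_codons)) { reason[i] <- "no-stop"; next }
    if (length(codons) > 2L &&
        any(codons[2:(length(codons) - 1L)] %in% stop_codons)) {
      reason[i] <- "internal-stop"; next
    }
  }

  # exact-duplicate removal among structurally valid records, first kept
  ok <- which(is.na(reason))
  dup <- ok[duplicated(seqs[ok])]
  reason[dup] <- "redundant"

  df <- data.frame(id = hd$id, description = hd$description,
                   sequence = seqs, rejection_reason = reason,
                   stringsAsFactors = FALSE)
  acc <- df[is.na(df$rejection_reason),
            c("id", "description", "sequence"), drop = FALSE]
  rej <- df[!is.na(df$rejection_reason), , drop = FALSE]
  rownames(acc) <- NULL
  rownames(rej) <- NULL
  list(accepted = acc, rejected = rej)
}

#' Write a segment table
#'
#' Writes segments as a tab-separated table with 1-based inclusive
#' coordinates (internal coordinates are 0-based half-open), sizes in kb
#' and GC to full precision.
#'
#' @param segments Segment data frame from [segment_chromosome()] or
#'   [segment_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(segments, path) {
  out <- data.frame(
    name = if ("name" %in% names(segments)) segments$name else "",
    chromosome = segments$chrom,
    start = segments$start + 1L,
    end = segments$end,
    size_kb = segments$size / 1000,
    gc_percent = segments$gc_percent,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a segment table written by [write_segment_table()]
#'
#' @param path Path to the TSV file.
#' @return Segment data frame with internal 0-based half-open coordinates.
#' @export
read_segment_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(
    chrom = as.character(tab$chromosome),
    start = as.integer(tab$start) - 1L,
    end = as.integer(tab$end),
    size = as.numeric(tab$size_kb) * 1000,
    gc_percent = tab$gc_percent,
    name = as.character(tab$name),
    stringsAsFactors = FALSE
  )
}

#' Write segments as BED
#'
#' BED uses 0-based half-open coordinates; the name field carries the
#' conventional segment name and the score field the GC level.
#'
#' @inheritParams write_segment_table
#' @export
write_segments_bed <- function(segments, path) {
  out <- data.frame(
    chrom = segments$chrom,
    start = segments$start,
    end = segments$end,
    name = if ("name" %in% names(segments)) segments$name else ".",
    score = round(segments$gc_percent, 2)
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
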
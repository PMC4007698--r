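# Independent oracles and fixture builders. These deliberately use a
# different implementation style from the package (character vectors,
# explicit loops, mean() recomputed from scratch) so that agreement is
# informative.

# GC% by character counting
oracle_gc <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  gc <- sum(ch %in% c("G", "C"))
  at <- sum(ch %in% c("A", "T"))
  if (gc + at == 0) return(NA_real_)
  100 * gc / (gc + at)
}

# greedy mean-tracking segmentation written independently: returns the
# vector of member counts per segment plus each segment's mean GC
oracle_segment <- function(gcs, threshold) {
  groups <- list()
  current <- numeric(0)
  for (g in gcs) {
    if (length(current) == 0) {
      current <- g
    } else if (abs(g - mean(current)) <= threshold) {
      current <- c(current, g)
    } else {
      groups[[length(groups) + 1]] <- current
      current <- g
    }
  }
  if (length(current)) groups[[length(groups) + 1]] <- current
  list(sizes = vapply(groups, length, 0L),
       means = vapply(groups, mean, 0))
}

# per-position GC of a CDS by explicit codon loop
oracle_codon_gc <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  stopifnot(length(ch) %% 3 == 0)
  gc_counts <- c(0, 0, 0)
  n_cod <- 0
  for (i in seq(1, length(ch), by = 3)) {
    cod <- ch[i:(i + 2)]
    if (!all(cod %in% c("A", "C", "G", "T"))) next
    n_cod <- n_cod + 1
    for (k in 1:3) gc_counts[k] <- gc_counts[k] + (cod[k] %in% c("G", "C"))
  }
  if (n_cod == 0) return(c(NA, NA, NA, NA))
  pos <- 100 * gc_counts / n_cod
  c(mean(pos), pos)
}

# per-bin bp totals by explicit loop over segments
oracle_bin <- function(gc, size, bin_width = 0.5) {
  tally <- new.env()
  for (i in seq_along(gc)) {
    key <- as.character(floor(gc[i] / bin_width) * bin_width)
    tally[[key]] <- (if (is.null(tally[[key]])) 0 else tally[[key]]) + size[i]
  }
  keys <- sort(as.numeric(ls(tally)))
  data.frame(bin_start = keys,
             weight_bp = vapply(as.character(keys),
                                function(k) tally[[k]], 0))
}

# window data frame for segmentation tests (all windows one chromosome,
# contiguous, valid unless stated)
make_windows <- function(gcs, valid = TRUE, ws = 25000L, chrom = "chr1") {
  n <- length(gcs)
  data.frame(chrom = rep_len(chrom, n),
             start = (seq_len(n) - 1L) * ws,
             end = seq_len(n) * ws,
             gc_percent = gcs,
             valid = rep_len(valid, n),
             stringsAsFactors = FALSE)
}

# deterministic sequence with an exact number of G+C bases
make_seq_gc <- function(len, gc_percent) {
  ngc <- round(len * gc_percent / 100)
  paste0(strrep("G", ngc), strrep("A", len - ngc))
}

# random CDS with valid start/stop, optional ambiguity codes
random_cds <- function(n_codons, p_ambig = 0) {
  inner <- n_codons - 2L
  alpha <- c("A", "C", "G", "T")
  body <- character(0)
  if (inner > 0) {
    cods <- replicate(inner, {
      cod <- sample(alpha, 3, replace = TRUE)
      if (p_ambig > 0 && runif(1) < p_ambig) cod[sample(3, 1)] <- "N"
      cod <- paste(cod, collapse = "")
      # avoid internal stops
      while (cod %in% c("TAA", "TAG", "TGA")) {
        cod <- paste(sample(alpha, 3, replace = TRUE), collapse = "")
      }
      cod
    })
    body <- paste(cods, collapse = "")
  }
  paste0("ATG", body, "TAA")
}
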
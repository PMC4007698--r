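#' Specification of one compositional family for genome simulation
#'
#' @param mean_gc Family mean GC in % (0 < mean_gc < 100).
#' @param proportion Fraction of the genome drawn from this family;
#'   proportions across a [genome_spec()] must sum to 1.
#' @param segment_length_mean,segment_length_sd Gaussian segment-length
#'   parameters in bases; lengths are truncated at one window and rounded
#'   to whole windows so the simulated truth aligns with the window grid.
#'   The 100-kb default mean matches the typical size of compositionally
#'   homogeneous segments in small eukaryotic genomes.
#' @return List of class `family_spec`.
#' @export
family_spec <- function(mean_gc, proportion,
                        segment_length_mean = 100000,
                        segment_length_sd = 50000) {
  stopifnot(mean_gc > 0, mean_gc < 100, proportion > 0, proportion <= 1,
            segment_length_mean > 0, segment_length_sd >= 0)
  structure(list(mean_gc = mean_gc, proportion = proportion,
                 segment_length_mean = segment_length_mean,
                 segment_length_sd = segment_length_sd),
            class = "family_spec")
}

#' Specification of a synthetic compartmentalized genome
#'
#' Describes a genome that is a mosaic of segments drawn from a small
#' number of GC families, the structure the compositional pipeline is
#' designed to recover.
#'
#' @param families List of [family_spec()] objects; proportions must sum
#'   to 1.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bases (rounded
#'   down to a whole number of windows); must be at least 10 windows.
#' @param window_noise_sd Gaussian sd, in % GC, of per-window target GC
#'   around the family mean at the 25-kb scale. 1% GC is typical of the
#'   local scatter seen in real window profiles.
#' @param window_size Window grid in bases (default 25 kb).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return List of class `genome_spec`.
#' @export
genome_spec <- function(families, n_chromosomes = 3L,
                        chromosome_length = 2000000L,
                        window_noise_sd = 1.0, window_size = 25000L,
                        seed = 1L) {
  if (inherits(families, "family_spec")) families <- list(families)
  stopifnot(length(families) >= 1L,
            all(vapply(families, inherits, TRUE, "family_spec")))
  props <- vapply(families, `[[`, 0, "proportion")
  if (abs(sum(props) - 1) > 1e-6) {
    stop("family proportions must sum to 1 (got ", sum(props), ")",
         call. = FALSE)
  }
  window_size <- as.integer(window_size)
  stopifnot(n_chromosomes >= 1L, window_noise_sd >= 0,
            chromosome_length >= 10L * window_size)
  structure(list(families = families,
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.numeric(chromosome_length),
                 window_noise_sd = window_noise_sd,
                 window_size = window_size,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# one window of i.i.d. bases at a target GC; G:C and A:T split evenly
BASE_LUT <- charToRaw("GCAT")

random_window_raw <- function(ws, gc_target, gc_skew = 0) {
  pg <- gc_target / 200 * (1 + gc_skew)
  pc <- gc_target / 100 - pg
  pa <- (1 - gc_target / 100) / 2
  BASE_LUT[sample.int(4L, ws, replace = TRUE,
                      prob = c(pg, pc, pa, 1 - pg - pc - pa))]
}

#' Simulate a compartmentalized genome with known ground truth
#'
#' Each chromosome is a concatenation of segments. A segment's family is
#' drawn by the family proportions, its length from the family's
#' (truncated, window-rounded) Gaussian; each window of the segment gets
#' a target GC equal to the family mean plus Gaussian noise, and bases
#' are drawn i.i.d. with P(G or C) = target/100, split evenly between G
#' and C and between A and T.
#'
#' @param spec A [genome_spec()].
#' @return List with `assembly` (named [Biostrings::DNAStringSet]),
#'   `truth_segments` (data frame: chrom, start, end, family,
#'   family_mean_gc; 0-based half-open), `truth_windows` (data frame:
#'   chrom, start, end, target_gc, family), `truth_families` (data
#'   frame: family, mean_gc, proportion_target, bp, realized_fraction)
#'   and `spec`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  ws <- spec$window_size
  k <- length(spec$families)
  props <- vapply(spec$families, `[[`, 0, "proportion")
  fmeans <- vapply(spec$families, `[[`, 0, "mean_gc")
  seqs <- character(spec$n_chromosomes)
  truth <- list()
  win_truth <- list()
  for (chr in seq_len(spec$n_chromosomes)) {
    chrom_id <- paste0("chr", chr)
    n_win <- as.integer(spec$chromosome_length %/% ws)
    filled <- 0L
    buf <- raw(n_win * ws)
    while (filled < n_win) {
      fam <- sample.int(k, 1L, prob = props)
      fs <- spec$families[[fam]]
      len_w <- max(1L, as.integer(round(
        stats::rnorm(1L, fs$segment_length_mean, fs$segment_length_sd) / ws)))
      len_w <- min(len_w, n_win - filled)
      targets <- pmin(100, pmax(0, stats::rnorm(len_w, fs$mean_gc,
                                                spec$window_noise_sd)))
      for (w in seq_len(len_w)) {
        ofs <- (filled + w - 1L) * ws
        buf[(ofs + 1L):(ofs + ws)] <- random_window_raw(ws, targets[w])
      }
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom_id,
        start = filled * ws,
        end = (filled + len_w) * ws,
        family = fam,
        family_mean_gc = fs$mean_gc,
        stringsAsFactors = FALSE)
      win_truth[[length(win_truth) + 1L]] <- data.frame(
        chrom = chrom_id,
        start = (filled + seq_len(len_w) - 1L) * ws,
        end = (filled + seq_len(len_w)) * ws,
        target_gc = targets,
        family = fam,
        stringsAsFactors = FALSE)
      filled <- filled + len_w
    }
    seqs[chr] <- rawToChar(buf)
  }
  truth_segments <- do.call(rbind, c(truth, make.row.names = FALSE))
  bp <- vapply(seq_len(k), function(f) {
    sum(as.numeric(truth_segments$end[truth_segments$family == f] -
                     truth_segments$start[truth_segments$family == f]))
  }, 0)
  truth_families <- data.frame(
    family = seq_len(k), mean_gc = fmeans, proportion_target = props,
    bp = bp, realized_fraction = bp / sum(bp))
  assembly <- Biostrings::DNAStringSet(seqs)
  names(assembly) <- paste0("chr", seq_len(spec$n_chromosomes))
  list(assembly = assembly, truth_segments = truth_segments,
       truth_windows = do.call(rbind, c(win_truth, make.row.names = FALSE)),
       truth_families = truth_families, spec = spec)
}

#' Specification of a synthetic ortholog CDS set
#'
#' Describes paired coding-sequence sets for two species whose
#' codon-position GC structure is controlled: per-gene (GC1, GC2, GC3)
#' targets for species A are drawn from a trivariate Gaussian with a
#' common between-position correlation, and species B repeats the same
#' targets with GC3 shifted -- the scenario of two related genomes under
#' divergent compositional pressure acting mostly at the third position.
#'
#' @param n_genes Number of ortholog pairs (>= 3).
#' @param means Length-3 numeric, target means of (GC1, GC2, GC3) for
#'   species A, in %.
#' @param sds Length-3 numeric, target sds in %.
#' @param correlation Common correlation between the three positions'
#'   targets; must keep the correlation matrix positive definite
#'   (> -0.5).
#' @param gc3_shift Added to species B's GC3 target, in % (negative
#'   shifts B towards lower GC3).
#' @param codons_per_gene Codons per CDS, including the forced start and
#'   stop codons. 300 codons is a typical gene length.
#' @param seed Integer seed.
#' @return List of class `ortholog_spec`.
#' @export
ortholog_spec <- function(n_genes = 4000L,
                          means = c(gc1 = 50, gc2 = 42, gc3 = 45),
                          sds = c(gc1 = 6, gc2 = 6, gc3 = 5),
                          correlation = 0.5,
                          gc3_shift = -25,
                          codons_per_gene = 300L,
                          seed = 1L) {
  stopifnot(n_genes >= 3L, length(means) == 3L, length(sds) == 3L,
            all(means > 0), all(means < 100), all(sds >= 0),
            correlation > -0.5, correlation < 1, codons_per_gene >= 3L)
  structure(list(n_genes = as.integer(n_genes), means = unname(means),
                 sds = unname(sds), correlation = correlation,
                 gc3_shift = gc3_shift,
                 codons_per_gene = as.integer(codons_per_gene),
                 seed = as.integer(seed)),
            class = "ortholog_spec")
}

# CDS whose per-position base draws realize target (gc1,gc2,gc3) in
# expectation; first codon ATG, last codon TAA. Internal stop codons
# are resampled so generated CDS always pass the structural cleanup
# rules (the resulting GC bias is negligible: ~3% of codons affected).
random_cds_raw <- function(n_codons, gc123) {
  draw <- function(n) {
    vapply(1:3, function(k) {
      p <- gc123[k] / 100
      sample.int(4L, n, replace = TRUE,
                 prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2))
    }, integer(n))
  }
  codes <- draw(n_codons)  # n_codons x 3, columns = codon positions
  lut_chr <- c("G", "C", "A", "T")
  codon_str <- function(cd) {
    paste0(lut_chr[cd[, 1L]], lut_chr[cd[, 2L]], lut_chr[cd[, 3L]])
  }
  bad <- which(codon_str(codes) %in% c("TAA", "TAG", "TGA"))
  while (length(bad)) {
    codes[bad, ] <- draw(length(bad))
    bad <- bad[codon_str(codes[bad, , drop = FALSE]) %in%
                 c("TAA", "TAG", "TGA")]
  }
  m <- matrix(BASE_LUT[t(codes)], nrow = 3L)
  m[, 1L] <- charToRaw("ATG")
  m[, n_codons] <- charToRaw("TAA")
  rawToChar(as.vector(m))
}

#' Simulate paired ortholog CDS sets with known ground truth
#'
#' @param spec An [ortholog_spec()].
#' @return List with `cds_a`, `cds_b` (named [Biostrings::DNAStringSet]),
#'   `pairs` (data frame `id_a`, `id_b`), and `truth` (list with the
#'   per-gene target matrices `targets_a`, `targets_b` and the spec).
#' @export
simulate_orthologs <- function(spec) {
  stopifnot(inherits(spec, "ortholog_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  rho <- spec$correlation
  R <- matrix(rho, 3L, 3L); diag(R) <- 1
  Sigma <- diag(spec$sds) %*% R %*% diag(spec$sds)
  a <- MASS::mvrnorm(n, mu = spec$means, Sigma = Sigma)
  a <- pmin(pmax(a, 0), 100)
  b <- a
  b[, 3L] <- pmin(pmax(a[, 3L] + spec$gc3_shift, 0), 100)
  nc <- spec$codons_per_gene
  seq_a <- vapply(seq_len(n), function(i) random_cds_raw(nc, a[i, ]), "")
  seq_b <- vapply(seq_len(n), function(i) random_cds_raw(nc, b[i, ]), "")
  ids_a <- sprintf("geneA_%05d", seq_len(n))
  ids_b <- sprintf("geneB_%05d", seq_len(n))
  cds_a <- Biostrings::DNAStringSet(stats::setNames(seq_a, ids_a))
  cds_b <- Biostrings::DNAStringSet(stats::setNames(seq_b, ids_b))
  colnames(a) <- colnames(b) <- c("gc1", "gc2", "gc3")
  list(cds_a = cds_a, cds_b = cds_b,
       pairs = data.frame(id_a = ids_a, id_b = ids_b,
                          stringsAsFactors = FALSE),
       truth = list(targets_a = a, targets_b = b, spec = spec))
}
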
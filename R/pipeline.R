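#' End-to-end compositional profile of a genome
#'
#' Runs the full pipeline -- windows, segments, 0.5%-GC binning, family
#' detection and classification -- and writes the window table, segment
#' table, binned profile and family table as TSV files. Progress and
#' quality counts (windows, discarded remainders, invalid windows) are
#' reported via [message()].
#'
#' @param genome Path to a genome FASTA or a [Biostrings::DNAStringSet].
#' @param out_dir Output directory (created if needed).
#' @param params A [segmentation_params()].
#' @param boundaries A [family_boundaries()].
#' @param bin_width Profile bin width in % GC.
#' @param species Optional binomial name used for segment names and the
#'   family table.
#' @param min_family_fraction,smooth_bins Passed to [detect_families()].
#' @return Invisibly, a list with `windows`, `segments`, `profile`,
#'   `families`, `family_table` and the output paths.
#' @export
run_profile <- function(genome, out_dir,
                        params = segmentation_params(),
                        boundaries = family_boundaries(),
                        bin_width = 0.5, species = NULL,
                        min_family_fraction = 0.02, smooth_bins = 3L) {
  assembly <- if (is.character(genome)) read_fasta(genome) else genome
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sg <- segment_genome(assembly, params, species = species)
  n_invalid <- sum(!sg$windows$valid)
  discarded <- sum(Biostrings::width(assembly) %% params$window_size)
  message(sprintf(
    "profile: %d records, %d windows (%d invalid), %d bases of trailing remainder discarded",
    length(assembly), nrow(sg$windows), n_invalid, discarded))
  profile <- bin_segments(sg$segments, bin_width = bin_width)
  fams <- detect_families(profile, min_family_fraction = min_family_fraction,
                          smooth_bins = smooth_bins)
  fams$label <- classify_family(fams$mean_gc, boundaries)
  ft <- family_table(fams, species = if (is.null(species)) "" else species,
                     boundaries = boundaries)
  paths <- list(
    windows = file.path(out_dir, "windows.tsv"),
    segments = file.path(out_dir, "segments.tsv"),
    profile = file.path(out_dir, "profile.tsv"),
    families = file.path(out_dir, "families.tsv"))
  write.table(sg$windows, paths$windows, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_segment_table(sg$segments, paths$segments)
  write_profile_table(profile, paths$profile)
  write.table(ft, paths$families, sep = "\t", quote = FALSE,
              row.names = FALSE)
  message(sprintf("profile: %d segments, %d famil%s detected",
                  nrow(sg$segments), nrow(fams),
                  if (nrow(fams) == 1L) "y" else "ies"))
  invisible(list(windows = sg$windows, segments = sg$segments,
                 profile = profile, families = fams, family_table = ft,
                 paths = paths))
}

#' Scaffold statistics for one or more assemblies
#'
#' One output row per assembly with genome GC, record count and the
#' megabase/percentage split of DNA around the length cutoff, rounded to
#' one decimal at the reporting layer only.
#'
#' @param genomes Character vector of FASTA paths, or a (possibly named)
#'   list of [Biostrings::DNAStringSet] assemblies.
#' @param out_dir Optional output directory; when given, the table is
#'   written to `scaffold_stats.tsv` there.
#' @param cutoff Length cutoff in bases.
#' @return Data frame with columns `assembly`, `gc_percent`, `n_records`,
#'   `total_mb`, `mb_below`, `mb_at_or_above`, `pct_below`,
#'   `pct_at_or_above` (full precision; use `round()` for display).
#' @export
run_scaffold_stats <- function(genomes, out_dir = NULL, cutoff = 100000L) {
  if (is.character(genomes)) {
    nm <- if (!is.null(names(genomes))) names(genomes) else basename(genomes)
    genomes <- stats::setNames(lapply(genomes, read_fasta), nm)
  }
  if (!is.list(genomes)) genomes <- list(assembly = genomes)
  if (is.null(names(genomes))) {
    names(genomes) <- paste0("assembly", seq_along(genomes))
  }
  rows <- lapply(names(genomes), function(nm) {
    st <- scaffold_stats(genomes[[nm]], cutoff = cutoff)
    data.frame(assembly = nm, gc_percent = st$gc_percent,
               n_records = st$n_records, total_mb = st$total_mb,
               mb_below = st$mb_below_cutoff,
               mb_at_or_above = st$mb_at_or_above_cutoff,
               pct_below = st$pct_below,
               pct_at_or_above = st$pct_at_or_above,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rep_out <- out
    num <- vapply(rep_out, is.numeric, TRUE)
    rep_out[num] <- lapply(rep_out[num], round, digits = 1)
    write.table(rep_out, file.path(out_dir, "scaffold_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Codon-position GC analysis of an ortholog pairing
#'
#' Cleans both CDS sets (logging rejection counts by reason), restricts
#' the pairing to genes accepted on both sides, computes per-gene
#' GC/GC1/GC2/GC3, the per-species distributions with between-species
#' overlaps, and all pairwise major-axis fits; writes `distributions.tsv`
#' and `fits.tsv`.
#'
#' @param cds_a,cds_b CDS FASTA paths or [Biostrings::DNAStringSet]s for
#'   species A and B.
#' @param pairs Two-column data frame (`id_a`, `id_b`) or path to a TSV
#'   with those columns. Pairs referencing unknown or rejected ids are
#'   dropped with a warning.
#' @param out_dir Output directory.
#' @param bin_width Histogram bin width in %.
#' @param method Regression flavour, see [orthogonal_regression()].
#' @param ... Passed to [clean_cds()].
#' @return Invisibly, a list with `gc_a`, `gc_b`, `distributions`,
#'   `fits`, `n_pairs` and the output paths.
#' @export
run_codon <- function(cds_a, cds_b, pairs, out_dir, bin_width = 2.5,
                      method = "ma", ...) {
  if (is.character(cds_a)) cds_a <- read_fasta(cds_a)
  if (is.character(cds_b)) cds_b <- read_fasta(cds_b)
  if (is.character(pairs)) pairs <- read.delim(pairs,
                                               stringsAsFactors = FALSE)
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  clean <- lapply(list(a = cds_a, b = cds_b), clean_cds, ...)
  for (sp in c("a", "b")) {
    rej <- clean[[sp]]$rejected
    if (nrow(rej)) {
      tab <- table(rej$rejection_reason)
      message("species ", sp, ": rejected ", nrow(rej), " CDS (",
              paste(names(tab), tab, sep = "=", collapse = ", "), ")")
    }
  }
  acc_a <- clean$a$accepted; acc_b <- clean$b$accepted
  keep <- pairs$id_a %in% acc_a$id & pairs$id_b %in% acc_b$id
  if (any(!keep)) {
    warning(sum(!keep), " pair(s) dropped: unknown or rejected ids")
  }
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 3L) {
    stop("fewer than 3 surviving ortholog pairs", call. = FALSE)
  }
  gc_a <- codon_gc_table(acc_a[match(pairs$id_a, acc_a$id), ])
  gc_b <- codon_gc_table(acc_b[match(pairs$id_b, acc_b$id), ])
  dists <- gc_distributions(gc_a, gc_b, bin_width = bin_width)
  fits <- pairwise_position_fits(gc_a, gc_b, method = method)
  paths <- list(distributions = file.path(out_dir, "distributions.tsv"),
                fits = file.path(out_dir, "fits.tsv"))
  write.table(dists$histograms, paths$distributions, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fits, paths$fits, sep = "\t", quote = FALSE,
              row.names = FALSE)
  message(sprintf("codon: %d ortholog pairs analysed", nrow(pairs)))
  invisible(list(gc_a = gc_a, gc_b = gc_b, distributions = dists,
                 fits = fits, n_pairs = nrow(pairs), paths = paths))
}

#' Write a simulated genome to disk
#'
#' Delegates to [simulate_genome()] and writes the FASTA plus the truth
#' segment and family tables; rerunning with the same spec reproduces
#' the files byte-identically.
#'
#' @param spec A [genome_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the [simulate_genome()] result with `paths` added.
#' @export
run_simulate_genome <- function(spec, out_dir) {
  sim <- simulate_genome(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(out_dir, "genome.fa"),
                truth_segments = file.path(out_dir, "truth_segments.tsv"),
                truth_families = file.path(out_dir, "truth_families.tsv"))
  write_fasta(sim$assembly, paths$fasta)
  write.table(sim$truth_segments, paths$truth_segments, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth_families, paths$truth_families, sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf(
    "simulated genome: %d chromosomes, %.1f Mb, %d families, %d truth segments",
    length(sim$assembly),
    sum(Biostrings::width(sim$assembly)) / 1e6,
    nrow(sim$truth_families), nrow(sim$truth_segments)))
  sim$paths <- paths
  invisible(sim)
}

#' Write a simulated ortholog set to disk
#'
#' @param spec An [ortholog_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the [simulate_orthologs()] result with `paths`
#'   added.
#' @export
run_simulate_orthologs <- function(spec, out_dir) {
  sim <- simulate_orthologs(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(cds_a = file.path(out_dir, "cds_a.fa"),
                cds_b = file.path(out_dir, "cds_b.fa"),
                pairs = file.path(out_dir, "pairs.tsv"))
  write_fasta(sim$cds_a, paths$cds_a)
  write_fasta(sim$cds_b, paths$cds_b)
  write.table(sim$pairs, paths$pairs, sep = "\t", quote = FALSE,
              row.names = FALSE)
  message(sprintf("simulated orthologs: %d pairs, %d codons per gene",
                  nrow(sim$pairs), sim$truth$spec$codons_per_gene))
  sim$paths <- paths
  invisible(sim)
}
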